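# End-to-end behaviour of the two engines (ctsplice with model = "simple" /
# "full").

test_that("pairing-only engine reproduces the closed-form skipping probability", {
  g <- two_intron_gene()
  # speed 6 kb/min -> T1 = 0.55 min; 1.5 kb/min -> 2.2 min; Inf -> PTS
  cases <- expand.grid(kp0 = c(0.5, 1, 2), speed = c(1.5, 3, 6))
  for (r in seq_len(nrow(cases))) {
    kp0 <- cases$kp0[r]; speed <- cases$speed[r]
    T1 <- (300 + 3000) / (1000 * speed)
    fit <- ctsplice(g, splice_rates(2, kp0 = kp0),
                    elongation = elongation_profile(speed))
    expect_equal(1 - inclusion(fit, 2), skip_closed_form(kp0, T1),
                 tolerance = 1e-9,
                 label = sprintf("skip(kp0=%g, speed=%g)", kp0, speed))
  }
  # purely post-transcriptional: the three-way equal race skips 1/3
  pts <- ctsplice(g, splice_rates(2, kp0 = 1),
                  elongation = elongation_profile(Inf))
  expect_equal(1 - inclusion(pts, 2), 1 / 3, tolerance = 1e-12)
})

test_that("instantaneous elongation equals the PTS limit in both engines", {
  for (model in c("simple", "full")) {
    g <- if (model == "full") three_intron_gene() else
      gene_structure(c(100, 80, 120, 60, 90), c(400, 900, 250, 700), "m4")
    r <- splice_rates(g$n_introns)
    fast <- ctsplice(g, r, elongation = elongation_profile(Inf),
                     model = model)
    # independent PTS oracle: a single absorbing solve over the complete
    # generator with every splice site synthesized
    space <- if (model == "simple")
      enumerate_simple_states(g$n_introns) else
        enumerate_full_states(g$n_introns)
    G <- build_generator(space, g, r)
    theta <- absorb(c(1, numeric(space$n - 1L)), G,
                    absorbing = space$absorbing)
    pts <- collapse_isoforms(theta, space, g$gene_id)
    expect_equal(fast$isoforms$probability, pts$probability,
                 tolerance = 1e-9)
    # very fast but finite elongation converges to the same limit
    slow0 <- ctsplice(g, r, elongation = elongation_profile(1e9),
                      model = model)
    expect_equal(fast$isoforms$probability, slow0$isoforms$probability,
                 tolerance = 1e-5)
  }
})

test_that("full model marginalizes to the simple model when availability is instantaneous", {
  genes <- list(gene_structure(c(120, 300), 500, "n1"),
                two_intron_gene(), three_intron_gene())
  for (g in genes) {
    rs <- splice_rates(g$n_introns, kp0 = 1)
    rf <- splice_rates(g$n_introns, k5 = 1e6, k3 = 1e6, kp0 = 1)
    for (speed in c(3, Inf)) {
      el <- elongation_profile(speed)
      simple <- ctsplice(g, rs, elongation = el, model = "simple")
      full <- ctsplice(g, rf, elongation = el, model = "full")
      expect_equal(full$isoforms$probability, simple$isoforms$probability,
                   tolerance = 1e-6,
                   label = sprintf("%s (N=%d, speed=%g)", g$gene_id,
                                   g$n_introns, speed))
    }
  }
})

test_that("probability is conserved and mass ends on absorbing states", {
  g <- three_intron_gene()
  fit <- ctsplice(g, splice_rates(3), elongation = elongation_profile(2),
                  model = "full", trace = TRUE)
  expect_lt(fit$conservation, 1e-9)
  expect_equal(sum(fit$isoforms$probability), 1, tolerance = 1e-9)
  for (beta in fit$trace)
    expect_lt(abs(sum(beta) - 1), 1e-9)
  space <- enumerate_full_states(3)
  expect_true(all(fit$theta[!space$absorbing] == 0))
})

test_that("single-intron genes have exactly one isoform with probability 1", {
  g <- gene_structure(c(100, 200), 800, "n1")
  for (model in c("simple", "full")) {
    fit <- ctsplice(g, splice_rates(1), elongation = elongation_profile(3),
                    model = model)
    expect_equal(nrow(fit$isoforms), 1L)
    expect_equal(fit$isoforms$probability, 1, tolerance = 1e-12)
  }
})

test_that("blocked reactions force the expected deterministic outcomes", {
  g <- two_intron_gene()
  el <- elongation_profile(3)
  # no skipping pairing: the cassette exon is always included
  f1 <- ctsplice(g, splice_rates(2, kp = c("1-2" = 0)), elongation = el)
  expect_equal(inclusion(f1, 2), 1, tolerance = 1e-12)
  # both constitutive pairings blocked: only the joint skipping excision
  # can remove the introns, so the exon is always skipped
  f2 <- ctsplice(g, splice_rates(2, kp = c("1-1" = 0, "2-2" = 0)),
                 elongation = el, model = "full")
  expect_equal(inclusion(f2, 2), 0, tolerance = 1e-12)
  # disabling only the 3' availability of intron 1 does NOT force skipping:
  # if intron 2 is excised constitutively first, the skipping pairing is
  # blocked too and the transcript can never finish splicing — a rate-zero
  # trap the engine must report rather than renormalize away
  expect_error(ctsplice(g, splice_rates(2, k3 = c(0, 1)), elongation = el,
                        model = "full"),
               "trap")
})

test_that("skipping decreases monotonically with the protected-phase time and kp", {
  g <- two_intron_gene()
  skips_speed <- vapply(c(8, 6, 3, 1.5, 0.75), function(v)
    1 - inclusion(ctsplice(g, splice_rates(2, kp0 = 1),
                           elongation = elongation_profile(v)), 2),
    numeric(1L))
  expect_true(all(diff(skips_speed) < 0))  # slower polymerase, less skipping
  skips_kp <- vapply(c(0.25, 0.5, 1, 2, 4), function(kp0)
    1 - inclusion(ctsplice(g, splice_rates(2, kp0 = kp0),
                           elongation = elongation_profile(6)), 2),
    numeric(1L))
  expect_true(all(diff(skips_kp) < 0))
})

test_that("perfect fidelity decays with intron count under instantaneous elongation", {
  pf <- vapply(2:6, function(N) {
    g <- gene_structure(rep(150, N + 1), rep(1000, N), paste0("chain", N))
    fit <- ctsplice(g, splice_rates(N, kp0 = 1),
                    elongation = elongation_profile(Inf))
    skipped_histogram(fit)$probability[1L]
  }, numeric(1L))
  expect_true(all(diff(pf) < 0))
})

test_that("exon definition never decreases the targeted exon's inclusion", {
  g <- short_down_gene()
  el <- elongation_profile(3)
  base <- splice_rates(2, k3 = c(0.5, 1))
  off <- inclusion(ctsplice(g, base, definition_config(), el,
                            model = "full"), 2)
  prev <- off
  for (k3f in c(0.5, 1, 2, 5, 20)) {
    r <- splice_rates(2, k3 = c(0.5, 1), k3_fast = k3f)
    on <- inclusion(ctsplice(g, r,
                             definition_config(exon_definition = TRUE,
                                               exon_def_exons = 2L),
                             el, model = "full"), 2)
    expect_gte(on, off - 1e-12)
    expect_gte(on, prev - 1e-12)    # increasing in the stimulated rate
    prev <- on
  }
})

test_that("fit object methods are coherent", {
  g <- two_intron_gene()
  fit <- ctsplice(g, splice_rates(2, kp0 = 1),
                  elongation = elongation_profile(6))
  expect_output(print(fit), "simple model")
  s <- summary(fit)
  expect_s3_class(s, "summary.ctsplice")
  expect_equal(unname(s$inclusion["exon2"]), inclusion(fit, 2))
  expect_equal(sum(s$histogram$probability), 1, tolerance = 1e-9)
  cf <- coef(fit)
  expect_equal(unname(cf["kp0"]), 1)
  expect_equal(unname(cf[c("k5.1", "k3.1")]), c(2, 1))
  sim <- simulate(fit, nsim = 500, seed = 9)
  expect_equal(sum(sim$probability), 1, tolerance = 1e-12)
  expect_error(inclusion(fit, 1), "internal")
  expect_error(inclusion(fit, 3), "internal")
})
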