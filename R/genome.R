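# Cohort-level simulation: a synthetic gene-length sampler emulating the
# contrast between short-intron-dominated (fly-like) and long-intron-
# dominated (human-like) genomes, batch simulation under PTS/CTS with and
# without intron definition, and the exon-definition length scan.

#' Species-like gene length profile
#'
#' Log-normal length distributions for introns and exons. The `"fly-like"`
#' preset has a short-intron mode (median 70 nt, so most introns fall under
#' the 200 nt intron-definition threshold); the `"human-like"` preset has
#' kb-scale introns (median 1500 nt). Exons are median 140 nt in both. The
#' parameters are stored in the object and can be overridden.
#'
#' @param preset `"fly-like"` or `"human-like"`.
#' @param intron_meanlog,intron_sdlog,exon_meanlog,exon_sdlog optional
#'   overrides of the log-normal parameters.
#' @return An object of class `"length_profile"`.
#' @examples
#' species_length_profile("fly-like")
#' @export
species_length_profile <- function(preset = c("fly-like", "human-like"),
                                   intron_meanlog = NULL,
                                   intron_sdlog = NULL,
                                   exon_meanlog = NULL,
                                   exon_sdlog = NULL) {
  preset <- match.arg(preset)
  par <- if (preset == "fly-like")
    list(intron_meanlog = log(70), intron_sdlog = 0.8,
         exon_meanlog = log(140), exon_sdlog = 0.6)
  else
    list(intron_meanlog = log(1500), intron_sdlog = 1.2,
         exon_meanlog = log(140), exon_sdlog = 0.6)
  for (nm in names(par)) {
    ov <- get(nm)
    if (!is.null(ov)) par[[nm]] <- as.numeric(ov)[1L]
  }
  structure(c(list(preset = preset), par), class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat("Length profile '", x$preset, "': intron median ",
      round(exp(x$intron_meanlog)), " nt (sdlog ", x$intron_sdlog,
      "), exon median ", round(exp(x$exon_meanlog)), " nt (sdlog ",
      x$exon_sdlog, ")\n", sep = "")
  invisible(x)
}

#' Sample a synthetic gene cohort
#'
#' Draws exon and intron lengths independently from the profile's log-normal
#' distributions (rounded, floored at 1 nt). The caller's RNG state is
#' restored on exit, so a repeated call with the same seed yields the
#' identical cohort.
#'
#' @param profile a [species_length_profile()].
#' @param n_genes number of genes.
#' @param n_introns introns per gene.
#' @param seed integer seed.
#' @return A list of [gene_structure()] objects named `g001, g002, ...`.
#' @export
sample_genes <- function(profile, n_genes, n_introns, seed = 1) {
  stopifnot(inherits(profile, "length_profile"), n_genes >= 1,
            n_introns >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  out <- vector("list", n_genes)
  for (k in seq_len(n_genes)) {
    ex <- pmax(1, round(stats::rlnorm(n_introns + 1L, profile$exon_meanlog,
                                      profile$exon_sdlog)))
    io <- pmax(1, round(stats::rlnorm(n_introns, profile$intron_meanlog,
                                      profile$intron_sdlog)))
    out[[k]] <- gene_structure(ex, io, sprintf("g%03d", k))
  }
  names(out) <- vapply(out, function(g) g$gene_id, character(1L))
  out
}

#' Batch splicing simulation over a gene cohort
#'
#' Runs the pairing-only engine on every gene under each requested condition
#' and summarizes fidelity. Conditions: `"PTS"` (instantaneous elongation),
#' `"PTS+ID"` (PTS with intron definition), `"CTS"` (finite elongation
#' speed), `"CTS+ID"` (CTS with intron definition).
#'
#' @param genes list of [gene_structure()] objects (at most 9 introns each;
#'   over-limit genes are skipped with a warning).
#' @param conditions subset of `c("PTS", "PTS+ID", "CTS", "CTS+ID")`.
#' @param kp0 default pairing rate, per minute.
#' @param speed elongation speed for the CTS conditions, kb/min.
#' @param span_mode intron-definition span rule, see [definition_config()].
#' @return An object of class `"ctsplice_batch"`: `per_gene` (long data
#'   frame: `gene_id`, `condition`, `n_skipped`, `probability`), `fidelity`
#'   (`gene_id`, `condition`, `perfect_fidelity` = probability of skipping 0
#'   exons) and `summary` (per-condition unweighted mean over genes of the
#'   skipped-exon histogram).
#' @export
run_batch <- function(genes,
                      conditions = c("PTS", "PTS+ID", "CTS", "CTS+ID"),
                      kp0 = 1, speed = 3, span_mode = "lariat") {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (inherits(genes, "gene_structure")) genes <- list(genes)
  genes <- Filter(function(g) {
    if (g$n_introns > 9L) {
      warning("gene '", g$gene_id,
              "' has more than 9 introns; skipped", call. = FALSE)
      FALSE
    } else TRUE
  }, genes)
  if (length(genes) == 0L) stop("no usable genes", call. = FALSE)
  maxN <- max(vapply(genes, function(g) g$n_introns, integer(1L)))
  cond_setup <- function(cond) list(
    elongation = elongation_profile(
      if (grepl("^PTS", cond)) Inf else speed),
    config = definition_config(intron_definition = grepl("ID", cond),
                               span_mode = span_mode))
  per <- list()
  for (g in genes) {
    for (cond in conditions) {
      cs <- cond_setup(cond)
      fit <- ctsplice(g, splice_rates(g$n_introns, kp0 = kp0),
                      config = cs$config, elongation = cs$elongation,
                      model = "simple")
      h <- skipped_histogram(fit)
      per[[length(per) + 1L]] <- data.frame(
        gene_id = g$gene_id, condition = cond,
        n_skipped = h$n_skipped, probability = h$probability,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  fid <- per[per$n_skipped == 0L,
             c("gene_id", "condition", "probability")]
  names(fid)[3L] <- "perfect_fidelity"
  rownames(fid) <- NULL
  smry <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- per[per$condition == cond, , drop = FALSE]
    p <- vapply(0:(maxN - 1L), function(b) {
      x <- sub$probability[sub$n_skipped == b]
      if (length(x)) sum(x) / length(genes) else 0
    }, numeric(1L))
    data.frame(condition = cond, n_skipped = 0:(maxN - 1L),
               mean_probability = p, stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  structure(list(per_gene = per, fidelity = fid, summary = smry,
                 conditions = conditions, kp0 = kp0, speed = speed),
            class = "ctsplice_batch")
}

#' @export
print.ctsplice_batch <- function(x, digits = 4, ...) {
  ng <- length(unique(x$per_gene$gene_id))
  cat("Batch splicing simulation:", ng, "genes x",
      length(x$conditions), "conditions (kp0 =", x$kp0,
      "/min, CTS speed =", x$speed, "kb/min)\n")
  cat("Mean perfect-fidelity probability per condition:\n")
  for (cond in x$conditions) {
    m <- mean(x$fidelity$perfect_fidelity[x$fidelity$condition == cond])
    cat(sprintf("  %-8s %.*f\n", cond, digits, m))
  }
  invisible(x)
}

#' Exon-definition scan over downstream intron length
#'
#' For a two-intron gene whose cassette exon is targeted by exon definition,
#' computes the inclusion of the cassette exon as a function of the
#' downstream intron length, with and without the conditional 3' speed-up
#' (full engine). In `"weak"` mode the baseline 3' availability of the
#' upstream intron is unusually slow.
#'
#' @param downstream_lengths grid of downstream intron lengths (nt).
#' @param mode `"normal"` or `"weak"` cassette exon.
#' @param exons exon lengths of the template gene (cassette exon in the
#'   middle).
#' @param upstream_intron upstream intron length (nt).
#' @param k3_slow baseline 3' availability rate of the upstream intron; by
#'   default 0.5/min (`"normal"`) or 0.1/min (`"weak"`).
#' @param k5 5' availability rates, per minute.
#' @param k3_fast stimulated 3' rate under exon definition.
#' @param kp0 pairing rate, per minute.
#' @param speed elongation speed, kb/min.
#' @return A data frame with columns `downstream_length`, `inclusion_cts`
#'   (exon definition off), `inclusion_exondef` (on) and `difference`.
#' @export
exon_definition_scan <- function(downstream_lengths,
                                 mode = c("normal", "weak"),
                                 exons = c(300, 120, 300),
                                 upstream_intron = 1500,
                                 k3_slow = NULL, k5 = 2, k3_fast = 4,
                                 kp0 = 1, speed = 3) {
  mode <- match.arg(mode)
  if (is.null(k3_slow)) k3_slow <- if (mode == "normal") 0.5 else 0.1
  prof <- elongation_profile(speed)
  res <- lapply(downstream_lengths, function(L) {
    g <- gene_structure(exons, c(upstream_intron, L),
                        paste0("scanL", L))
    r <- splice_rates(2, k5 = k5, k3 = c(k3_slow, 1), kp0 = kp0,
                      k3_fast = k3_fast)
    off <- ctsplice(g, r, definition_config(), prof, model = "full")
    on <- ctsplice(g, r,
                   definition_config(exon_definition = TRUE,
                                     exon_def_exons = 2L),
                   prof, model = "full")
    data.frame(downstream_length = L,
               inclusion_cts = inclusion(off, 2),
               inclusion_exondef = inclusion(on, 2))
  })
  out <- do.call(rbind, res)
  out$difference <- out$inclusion_exondef - out$inclusion_cts
  out
}
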