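#' Simulate co-transcriptional alternative splicing of a gene
#'
#' Computes the probability of every fully spliced isoform of a gene under a
#' kinetic Markov-chain model of splicing coupled to polymerase elongation.
#' Splice sites become reactable in the temporal order of their synthesis;
#' within each transcriptional phase the enabled reactions compete as a
#' continuous-time Markov chain, propagated by matrix exponentials, and after
#' the last phase the chain is run to its absorbing limit (all introns
#' excised).
#'
#' Two engines are available. The `"simple"` engine models only the pairing
#' (joining) reactions, treating splice-site availability as instantaneous;
#' it scales to 9 introns. The `"full"` engine additionally models the 5' and
#' 3' availability reactions of every splice site (rates `k5`, `k3`), which
#' is required for exon definition and availability-rate pausing scenarios;
#' the combinatorial state space limits it to 3 introns.
#'
#' With `elongation_profile(Inf)` every finite phase has zero duration and
#' the result is purely post-transcriptional splicing (PTS); the same limit
#' is reached by setting all phase times to zero.
#'
#' @param gene a [gene_structure()].
#' @param rates a [splice_rates()]; defaults to `splice_rates(N)` for the
#'   gene's intron count.
#' @param config a [definition_config()] selecting intron/exon definition.
#' @param elongation an [elongation_profile()] (speed in kb/min, pauses).
#' @param model `"simple"` (pairing-only, up to 9 introns) or `"full"`
#'   (availability + pairing, up to 3 introns).
#' @param trace keep the per-phase probability vectors (for debugging).
#' @return An object of class `"ctsplice"` with components `isoforms` (an
#'   [isoform_distribution][collapse_isoforms()]), `theta` (named probability
#'   vector over the chain's states, mass on absorbing states only), `gene`,
#'   `rates`, `config`, `elongation`, `schedule`, `model`, `conservation`
#'   (largest probability-conservation residual seen) and, if requested,
#'   `trace`.
#' @examples
#' g <- gene_structure(c(300, 300, 300), c(3000, 3000))
#' fit <- ctsplice(g, splice_rates(2, kp0 = 1), elongation = elongation_profile(6))
#' fit
#' 1 - inclusion(fit, exon = 2)   # skipping probability of the cassette exon
#' @seealso [gillespie()] for the stochastic oracle, [run_batch()] for
#'   cohort simulations.
#' @export
ctsplice <- function(gene, rates = NULL, config = definition_config(),
                     elongation = elongation_profile(),
                     model = c("simple", "full"), trace = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(gene, "gene_structure"))
  N <- gene$n_introns
  if (is.null(rates)) rates <- splice_rates(N)
  stopifnot(inherits(rates, "splice_rates"))
  if (rates$N != N)
    stop("rates are for ", rates$N, " introns but gene has ", N,
         call. = FALSE)
  validate_config(config, gene)
  if (config$exon_definition && model != "full")
    stop("exon definition requires the full engine (model = \"full\")",
         call. = FALSE)
  schedule <- phase_schedule(gene, elongation, model)
  space <- if (model == "simple") enumerate_simple_states(N) else
    enumerate_full_states(N)
  res <- run_phases(space, gene, rates, config, schedule, trace)
  theta <- res$theta
  names(theta) <- space$key
  iso <- collapse_isoforms(theta, space, gene$gene_id)
  structure(
    list(isoforms = iso, theta = theta, gene = gene, rates = rates,
         config = config, elongation = elongation, schedule = schedule,
         model = model, conservation = res$conservation,
         trace = if (trace) res$trace else NULL, call = match.call()),
    class = "ctsplice")
}

# Phase-wise propagation. The probability vector starts as mass 1 on the
# root; for the simple engine it spans only the states reachable with the
# introns synthesized so far and is zero-padded as the space grows (the
# states are ordered to make these a prefix). Finite phases whose enabled
# reaction set already equals the terminal phase's, with no overrides in
# force then or later, are folded into the absorbing solve (a finite prefix
# does not change the absorbing limit of a fixed generator).
run_phases <- function(space, gene, rates, config, schedule, trace = FALSE) {
  n_full <- space$n
  beta <- c(1, numeric((if (space$model == "simple")
    sum(space$maxj <= schedule[[1L]]$n3) else n_full) - 1L))
  worst <- 0
  tr <- list()
  has_ov <- vapply(schedule, function(p) length(p$overrides) > 0L, logical(1L))
  later_ov <- rev(cumsum(rev(has_ov))) > 0
  for (k in seq_along(schedule)) {
    p <- schedule[[k]]
    if (is.infinite(p$duration)) break
    foldable <- !has_ov[k] && !later_ov[k] && p$n3 == space$N &&
      (space$model == "simple" || p$n5 == space$N)
    block <- if (space$model == "simple") sum(space$maxj <= p$n3) else n_full
    if (length(beta) < block) beta <- c(beta, numeric(block - length(beta)))
    if (p$duration > 0 && !foldable) {
      r <- apply_rate_overrides(rates, p$overrides)
      G <- build_generator(space, gene, r, config, n5 = p$n5, n3 = p$n3,
                           block = block)
      beta <- tryCatch(propagate(beta, G, p$duration),
                       error = function(e)
                         stop("phase ", k, " (", p$label, "): ",
                              conditionMessage(e), call. = FALSE))
      worst <- max(worst, abs(sum(beta) - 1))
      if (abs(sum(beta) - 1) > 1e-9)
        stop("probability not conserved after phase ", k, call. = FALSE)
    }
    if (trace) tr[[paste0("phase", k, ".", p$label)]] <- beta
  }
  if (length(beta) < n_full) beta <- c(beta, numeric(n_full - length(beta)))
  G <- build_generator(space, gene, rates, config,
                       n5 = space$N, n3 = space$N, block = n_full)
  theta <- absorb(beta, G, absorbing = space$absorbing,
                  state_keys = space$key)
  worst <- max(worst, abs(sum(theta) - 1))
  if (abs(sum(theta) - 1) > 1e-9)
    stop("probability not conserved by the absorbing limit", call. = FALSE)
  list(theta = theta, conservation = worst, trace = tr)
}

#' @export
print.ctsplice <- function(x, digits = 4, ...) {
  cat("Co-transcriptional splicing fit (", x$model, " model)\n", sep = "")
  cat("Gene '", x$gene$gene_id, "': ", x$gene$n_introns, " introns; speed ",
      if (is.infinite(x$elongation$speed)) "Inf (PTS)" else
        paste0(x$elongation$speed, " kb/min"), "\n", sep = "")
  iso <- x$isoforms
  top <- utils::head(iso[order(-iso$probability), , drop = FALSE], 5L)
  cat("Isoform probabilities",
      if (nrow(iso) > 5L) " (top 5)" else "", ":\n", sep = "")
  for (r in seq_len(nrow(top)))
    cat(sprintf("  %-10s (%d skipped)  %.*f\n",
                ifelse(top$isoform[r] == "", "(single)", top$isoform[r]),
                top$n_skipped[r], digits, top$probability[r]))
  invisible(x)
}

#' @export
summary.ctsplice <- function(object, ...) {
  N <- object$gene$n_introns
  internal <- if (N > 1L) 2:N else integer()
  structure(
    list(gene = object$gene, model = object$model,
         isoforms = object$isoforms,
         histogram = skipped_histogram(object$isoforms),
         inclusion = if (length(internal))
           stats::setNames(vapply(internal, function(e)
             inclusion(object$isoforms, e), numeric(1L)),
             paste0("exon", internal)) else numeric(),
         conservation = object$conservation,
         n_phases = length(object$schedule)),
    class = "summary.ctsplice")
}

#' @export
print.summary.ctsplice <- function(x, digits = 6, ...) {
  cat("Co-transcriptional splicing fit (", x$model, " model), gene '",
      x$gene$gene_id, "'\n", sep = "")
  print(x$isoforms, digits = digits)
  cat("Exons skipped:\n")
  print(format(x$histogram, digits = digits), row.names = FALSE)
  if (length(x$inclusion)) {
    cat("Internal exon inclusion:\n")
    print(round(x$inclusion, digits))
  }
  cat("Probability-conservation residual:", format(x$conservation), "\n")
  invisible(x)
}

#' @export
coef.ctsplice <- function(object, ...) {
  r <- object$rates
  kp <- r$kp[upper.tri(r$kp, diag = TRUE)]
  ij <- which(upper.tri(r$kp, diag = TRUE), arr.ind = TRUE)
  c(stats::setNames(r$k5, paste0("k5.", seq_len(r$N))),
    stats::setNames(r$k3, paste0("k3.", seq_len(r$N))),
    kp0 = r$kp0, k3_fast = r$k3_fast,
    stats::setNames(r$kp[ij], paste0("kp.", ij[, 1], ".", ij[, 2])))
}

#' Stochastic replication of a fitted splicing model
#'
#' Runs the Gillespie oracle on the fitted model's reaction system and phase
#' schedule, returning empirical isoform frequencies comparable to
#' `object$isoforms`.
#'
#' @param object a [ctsplice()] fit.
#' @param nsim number of stochastic trajectories.
#' @param seed integer seed.
#' @param ... unused.
#' @return See [gillespie()].
#' @export
simulate.ctsplice <- function(object, nsim = 10000, seed = 1, ...) {
  gillespie(object$gene, object$rates, object$config, object$schedule,
            n = nsim, seed = seed)
}

#' @export
plot.ctsplice <- function(x, ...) {
  h <- skipped_histogram(x$isoforms)
  graphics::barplot(h$probability, names.arg = h$n_skipped,
                    xlab = "exons skipped", ylab = "probability",
                    main = paste0("'", x$gene$gene_id, "' (", x$model,
                                  " model)"),
                    col = "steelblue", border = NA, ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
inclusion.ctsplice <- function(x, exon, ...) inclusion(x$isoforms, exon)

#' @export
skipped_histogram.ctsplice <- function(x, ...) skipped_histogram(x$isoforms)
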