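# Numerical core: matrix-exponential propagation of the phase-wise
# continuous-time Markov chain, the absorbing (t -> infinity) limit, and an
# exact stochastic (Gillespie) simulator used as an independent oracle.

#' Propagate a probability vector through one phase
#'
#' Computes `beta %*% expm(G * T)` for a generator matrix `G` (rows summing
#' to zero) and a finite phase duration `T` in minutes. Probability is
#' conserved by construction; the result is checked and tiny negative round-
#' off is clamped to zero.
#'
#' @param beta probability vector aligned to the generator's state order.
#' @param G dense generator matrix, e.g. from [build_generator()].
#' @param T phase duration in minutes (finite, >= 0).
#' @return The propagated probability vector.
#' @export
propagate <- function(beta, G, T) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0 ||
      is.infinite(T))
    stop("T must be a finite duration >= 0 (use absorb() for t -> Inf)",
         call. = FALSE)
  if (length(beta) != nrow(G))
    stop("length(beta) does not match dim(G)", call. = FALSE)
  if (T == 0) return(beta)
  out <- as.vector(beta %*% as.matrix(Matrix::expm(Matrix::Matrix(G * T))))
  if (any(!is.finite(out)))
    stop("non-finite probabilities after propagation", call. = FALSE)
  out[out < 0 & out > -1e-12] <- 0
  if (abs(sum(out) - sum(beta)) > 1e-9)
    stop("probability not conserved by propagation (residual ",
         format(sum(out) - sum(beta)), ")", call. = FALSE)
  out
}

#' Absorbing limit of the chain
#'
#' Moves all probability mass to the absorbing states, i.e. the limit of
#' [propagate()] as `T -> Inf`, computed by the absorbing-chain linear solve:
#' with transient block `G_tt` and transient-to-absorbing block `G_ta`, the
#' absorbed mass is `beta_a + beta_t %*% solve(-G_tt, G_ta)`.
#'
#' @param beta probability vector.
#' @param G dense generator matrix.
#' @param absorbing optional logical vector marking the true absorbing states
#'   (fully spliced products). When supplied, a transient state with no
#'   outgoing rate (a rate-zero trap) is reported as an error; when `NULL`,
#'   absorbing states are inferred as the zero rows of `G`.
#' @param state_keys optional state labels used in trap error messages.
#' @return Probability vector with mass only on absorbing states.
#' @export
absorb <- function(beta, G, absorbing = NULL, state_keys = NULL) {
  n <- nrow(G)
  zero_row <- rowSums(abs(G)) == 0
  if (is.null(absorbing)) absorbing <- zero_row
  # states reachable from the support of beta through positive-rate edges;
  # the solve is restricted to these (unreachable zero-rate rows would make
  # the transient block spuriously singular)
  reach <- beta > 1e-15
  repeat {
    new <- reach | (colSums(G[reach, , drop = FALSE] > 0) > 0)
    if (identical(new, reach)) break
    reach <- new
  }
  trap <- zero_row & !absorbing & reach
  if (any(trap))
    stop("rate-zero trap: no outgoing reaction from transient state ",
         if (!is.null(state_keys)) paste(state_keys[trap], collapse = ", ")
         else paste(which(trap), collapse = ", "), call. = FALSE)
  tr <- which(!absorbing & reach)
  ab <- which(absorbing)
  out <- numeric(n)
  out[ab] <- beta[ab]
  if (length(tr) && any(beta[tr] != 0)) {
    B <- tryCatch(solve(-G[tr, tr, drop = FALSE], G[tr, ab, drop = FALSE]),
                  error = function(e)
                    stop("singular transient block in absorbing solve: ",
                         conditionMessage(e), call. = FALSE))
    out[ab] <- out[ab] + as.vector(beta[tr] %*% B)
  }
  out[out < 0 & out > -1e-12] <- 0
  if (abs(sum(out) - sum(beta)) > 1e-9)
    stop("probability not conserved by absorbing solve", call. = FALSE)
  out
}

# Spectral construction of the t -> Inf limit kept as a cross-check of the
# linear solve (used in tests): zero out the contribution of every non-zero
# eigenvalue of the generator.
absorb_spectral <- function(beta, G) {
  eg <- eigen(t(G))
  V <- eg$vectors
  lam <- eg$values
  sel <- abs(lam) < 1e-9
  coef <- solve(V, as.complex(beta))
  out <- as.vector(V[, sel, drop = FALSE] %*% coef[sel])
  Re(out)
}

#' Stochastic (Gillespie) simulation of the splicing reaction system
#'
#' Simulates exact trajectories of the same reaction system integrated by the
#' matrix-exponential engine: availability and pairing reactions (full model)
#' or pairing reactions only (simple model), with the phase schedule gating
#' which splice sites exist. Waiting times are redrawn at phase boundaries,
#' which is exact for exponential waiting times. This simulator works
#' directly on the reaction representation, independently of the generator
#' matrices, and serves as the package's validation oracle.
#'
#' @param gene a [gene_structure()].
#' @param rates a [splice_rates()].
#' @param config a [definition_config()].
#' @param schedule a [phase_schedule()]; its model attribute selects the
#'   engine.
#' @param n number of trajectories.
#' @param seed integer seed for the trajectory stream (the caller's RNG state
#'   is restored on exit).
#' @return A data frame with one row per observed isoform: `isoform`
#'   (inclusion bitstring over internal exons, 5' to 3'), `count`,
#'   `probability` (empirical frequency) and `se` (binomial standard error).
#'   The number of trajectories is attached as attribute `n`.
#' @export
gillespie <- function(gene, rates, config = definition_config(), schedule,
                      n = 10000, seed = 1) {
  stopifnot(inherits(schedule, "phase_schedule"))
  model <- attr(schedule, "model")
  N <- gene$n_introns
  validate_config(config, gene)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  # per-phase rate tables (pause overrides applied)
  phases <- lapply(schedule, function(p) {
    r <- apply_rate_overrides(rates, p$overrides)
    PR <- matrix(0, N, N)
    for (i in 1:N) for (j in i:N)
      PR[i, j] <- pairing_rate(i, j, gene, r, config)
    list(duration = p$duration, n5 = p$n5, n3 = p$n3,
         k5 = r$k5, k3 = r$k3, k3_fast = r$k3_fast, PR = PR)
  })
  use_avail <- model == "full"
  counts <- integer(2L^(N - 1L))           # indexed by inclusion bit pattern
  for (traj in seq_len(n)) {
    a5 <- a3 <- rep(!use_avail, N)         # simple model: availability instant
    cov <- logical(N)
    skipped <- logical(max(N - 1L, 0L))    # internal exons 2..N
    for (ph in phases) {
      t_left <- ph$duration
      repeat {
        # enabled reactions and their rates
        rxr <- numeric(0); rxid <- list()
        if (use_avail) {
          for (s in seq_len(ph$n5)) if (!cov[s] && !a5[s] && ph$k5[s] > 0) {
            rxr <- c(rxr, ph$k5[s]); rxid[[length(rxid) + 1L]] <- c(1L, s, 0L)
          }
          for (s in seq_len(ph$n3)) if (!cov[s] && !a3[s]) {
            k <- if (config$exon_definition &&
                     (s + 1L) %in% config$exon_def_exons && s < N &&
                     a5[s + 1L]) ph$k3_fast else ph$k3[s]
            if (k > 0) {
              rxr <- c(rxr, k); rxid[[length(rxid) + 1L]] <- c(2L, s, 0L)
            }
          }
        }
        if (ph$n3 > 0) for (i in 1:N) for (j in i:N) {
          if (j > ph$n3) next              # 3'ss of intron j not yet made
          if (!a5[i] || !a3[j] || any(cov[i:j])) next
          if (ph$PR[i, j] > 0) {
            rxr <- c(rxr, ph$PR[i, j])
            rxid[[length(rxid) + 1L]] <- c(3L, i, j)
          }
        }
        total <- sum(rxr)
        if (total == 0) {
          if (is.infinite(t_left) && !all(cov))
            stop("gillespie: trajectory trapped with unspliced introns ",
                 "and no enabled reaction (a required rate is zero)",
                 call. = FALSE)
          break
        }
        dt <- stats::rexp(1L, total)
        if (dt > t_left) break             # memoryless: redraw next phase
        t_left <- t_left - dt
        rx <- rxid[[sample.int(length(rxr), 1L, prob = rxr)]]
        if (rx[1L] == 1L) a5[rx[2L]] <- TRUE
        else if (rx[1L] == 2L) a3[rx[2L]] <- TRUE
        else {
          i <- rx[2L]; j <- rx[3L]
          cov[i:j] <- TRUE
          if (j > i) skipped[i:(j - 1L)] <- TRUE  # internal exons i+1 .. j
        }
        if (all(cov)) break
      }
      if (all(cov)) break
    }
    if (!all(cov))
      stop("gillespie: trajectory did not reach absorption", call. = FALSE)
    idx <- if (N > 1L)
      1L + sum(2L^(seq_len(N - 1L) - 1L) * as.integer(!rev(skipped))) else 1L
    counts[idx] <- counts[idx] + 1L
  }
  labels <- isoform_labels(N)
  keep <- counts > 0L
  p <- counts / n
  res <- data.frame(isoform = labels[keep], count = counts[keep],
                    probability = p[keep], se = sqrt(p[keep] * (1 - p[keep]) / n),
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$probability, res$isoform), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n") <- n
  res
}
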