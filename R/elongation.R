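#' Polymerase elongation profile
#'
#' Describes how RNA polymerase II traverses the gene: a constant elongation
#' speed plus optional pauses. Speed is given in kb/min (`Inf` means
#' instantaneous elongation, i.e. purely post-transcriptional splicing). A
#' pause is anchored either immediately after the synthesis of a named splice
#' site, or within a gene element (exon or intron), and may carry rate
#' overrides that apply only while the polymerase is paused.
#'
#' @param speed elongation speed in kb/min (> 0, may be `Inf`).
#' @param pauses a list of [pol_pause()] objects.
#' @return An object of class `"elongation_profile"`.
#' @examples
#' elongation_profile(3)
#' elongation_profile(6, pauses = list(pol_pause("3ss", 1, 1 / 60)))
#' @export
elongation_profile <- function(speed = 3, pauses = list()) {
  speed <- as.numeric(speed)[1L]
  if (is.na(speed) || speed <= 0)
    stop("elongation speed must be > 0 kb/min", call. = FALSE)
  if (inherits(pauses, "pol_pause")) pauses <- list(pauses)
  if (!all(vapply(pauses, inherits, logical(1L), "pol_pause")))
    stop("'pauses' must be a list of pol_pause() objects", call. = FALSE)
  structure(list(speed = speed, pauses = pauses),
            class = "elongation_profile")
}

#' @export
print.elongation_profile <- function(x, ...) {
  cat("Elongation profile: speed =",
      if (is.infinite(x$speed)) "Inf (instantaneous; PTS)" else
        paste(x$speed, "kb/min"), "\n")
  for (p in x$pauses)
    cat("  pause: ", format_anchor(p), ", ", signif(p$duration * 60, 4),
        " s", if (length(p$overrides))
          paste0(", overrides: ",
                 paste(names(p$overrides), p$overrides, sep = "=",
                       collapse = ", ")) else "", "\n", sep = "")
  invisible(x)
}

#' Polymerase pause
#'
#' @param anchor one of `"5ss"`, `"3ss"` (pause immediately after that splice
#'   site of intron `index` is synthesized), `"exon"` or `"intron"` (pause
#'   while transcribing that element).
#' @param index 1-based index of the intron (for splice-site anchors) or of
#'   the exon/intron element.
#' @param duration pause duration in minutes (>= 0).
#' @param overrides optional named numeric vector of rate overrides applied
#'   during the pause, e.g. `c(k3.1 = 20)` sets the 3' availability rate of
#'   intron 1, `c(k5.2 = 10)` the 5' rate of intron 2; `kp0`, `k3_fast`,
#'   `kp.i.j`, and unsuffixed `k5`/`k3` (all introns) are also understood.
#' @return An object of class `"pol_pause"`.
#' @export
pol_pause <- function(anchor = c("3ss", "5ss", "exon", "intron"),
                      index, duration, overrides = NULL) {
  anchor <- match.arg(anchor)
  index <- as.integer(index)[1L]
  duration <- as.numeric(duration)[1L]
  if (is.na(duration) || duration < 0 || is.infinite(duration))
    stop("pause duration must be finite and >= 0 minutes", call. = FALSE)
  if (is.na(index) || index < 1L)
    stop("pause anchor index must be >= 1", call. = FALSE)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))) ||
        !is.numeric(overrides))
      stop("overrides must be a named numeric vector", call. = FALSE)
  }
  structure(list(anchor = anchor, index = index, duration = duration,
                 overrides = overrides),
            class = "pol_pause")
}

format_anchor <- function(p) {
  switch(p$anchor,
         "5ss" = paste0("after 5'ss of intron ", p$index),
         "3ss" = paste0("after 3'ss of intron ", p$index),
         exon = paste0("in exon ", p$index),
         intron = paste0("in intron ", p$index))
}

#' Transcriptional phase schedule
#'
#' Splits the transcription of a gene into phases during which a fixed set of
#' splice sites has been synthesized. Phase durations are element lengths
#' divided by the elongation speed. For the pairing-only (`"simple"`) engine
#' the schedule starts when intron 1 has been fully transcribed and phase `i`
#' (for `i < N`) spans exon `i+1` plus intron `i+1`; the last finite phase
#' covers the final exon, and a terminal infinite phase represents the
#' post-transcriptional completion of splicing. For the `"full"` engine the
#' schedule additionally splits at every splice-site synthesis point, starting
#' with a sub-phase over intron 1 during which only the 5' site of intron 1
#' exists. Pauses insert extra zero-elongation phases at their anchors.
#'
#' Each phase records `n5` and `n3`, the number of introns whose 5' and 3'
#' splice sites have been synthesized when the phase begins.
#'
#' @param gene a [gene_structure()].
#' @param profile an [elongation_profile()].
#' @param model `"simple"` or `"full"`; controls where the schedule starts and
#'   whether phases split at 5' splice-site synthesis points.
#' @return An object of class `"phase_schedule"`: a list of phases, each a
#'   list with `duration` (minutes; `Inf` for the terminal phase), `n5`, `n3`,
#'   `overrides` and `label`.
#' @examples
#' g <- gene_structure(c(300, 300, 300), c(3000, 3000))
#' phase_schedule(g, elongation_profile(3))
#' @export
phase_schedule <- function(gene, profile = elongation_profile(),
                           model = c("simple", "full")) {
  model <- match.arg(model)
  stopifnot(inherits(gene, "gene_structure"),
            inherits(profile, "elongation_profile"))
  N <- gene$n_introns
  v <- 1000 * profile$speed                # nt/min
  seg <- list()
  add <- function(len, n5, n3, label)
    seg[[length(seg) + 1L]] <<- list(duration = len / v, n5 = n5, n3 = n3,
                                     overrides = NULL, label = label)
  if (model == "full")
    add(gene$introns[1L], 1L, 0L, "intron 1")
  for (m in seq_len(N)[-1L]) {             # elements after intron 1
    add(gene$exons[m], m - 1L, m - 1L, paste("exon", m))
    add(gene$introns[m], if (model == "full") m else m - 1L, m - 1L,
        paste("intron", m))
  }
  add(gene$exons[N + 1L], N, N, paste("exon", N + 1L))
  seg[[length(seg) + 1L]] <- list(duration = Inf, n5 = N, n3 = N,
                                  overrides = NULL, label = "terminal")
  seg <- insert_pauses(seg, profile$pauses, gene, model)
  seg <- merge_phases(seg, model)
  structure(seg, class = "phase_schedule",
            gene_id = gene$gene_id, model = model, speed = profile$speed)
}

# Insert zero-elongation pause phases at their anchors. Splice-site anchors go
# immediately after the boundary at which the site is synthesized, so the
# pause phase carries the synthesized-site set of the segment that follows;
# element anchors pause within the element and keep its enabled set (the exact
# position within an element is immaterial under piecewise-constant rates).
insert_pauses <- function(seg, pauses, gene, model) {
  N <- gene$n_introns
  for (p in pauses) {
    pos <- NA_integer_   # insert *before* segment pos
    at_following <- TRUE # take n5/n3 from following (TRUE) or preceding seg
    if (p$anchor == "3ss") {
      if (p$index > N) stop("pause anchor outside gene: 3'ss of intron ",
                            p$index, call. = FALSE)
      if (p$index == 1L) {
        pos <- if (model == "full") 2L else 1L
      } else {
        pos <- seg_after(seg, paste("intron", p$index))
      }
    } else if (p$anchor == "5ss") {
      if (p$index > N) stop("pause anchor outside gene: 5'ss of intron ",
                            p$index, call. = FALSE)
      if (p$index == 1L) {
        if (model != "full")
          stop("a pause after the 5'ss of intron 1 precedes the simulated ",
               "region of the pairing-only model; use the full model",
               call. = FALSE)
        pos <- 1L
      } else {
        pos <- seg_after(seg, paste("exon", p$index))
      }
    } else if (p$anchor == "exon") {
      if (p$index < 2L || p$index > N + 1L)
        stop("pause anchor outside the simulated region: exon ", p$index,
             call. = FALSE)
      pos <- seg_after(seg, paste("exon", p$index))
      at_following <- FALSE
    } else {                               # intron element
      if (p$index > N || (p$index == 1L && model != "full"))
        stop("pause anchor outside the simulated region: intron ", p$index,
             call. = FALSE)
      pos <- seg_after(seg, paste("intron", p$index))
      at_following <- FALSE
    }
    ref <- if (at_following) seg[[pos]] else seg[[pos - 1L]]
    ph <- list(duration = p$duration, n5 = ref$n5, n3 = ref$n3,
               overrides = p$overrides, label = paste0("pause (",
                                                       format_anchor(p), ")"))
    seg <- append(seg, list(ph), after = pos - 1L)
  }
  seg
}

seg_after <- function(seg, label) {
  hit <- which(vapply(seg, function(s) identical(s$label, label), logical(1L)))
  if (length(hit) == 0L)
    stop("internal error: no segment labelled '", label, "'")
  hit[1L] + 1L
}

# Merge consecutive non-pause segments with identical enabled-site sets; for
# the simple engine exon m + intron m collapse into the single phase the
# schedule notation uses.
merge_phases <- function(seg, model) {
  out <- list(seg[[1L]])
  for (s in seg[-1L]) {
    last <- out[[length(out)]]
    mergeable <- is.null(s$overrides) && is.null(last$overrides) &&
      !grepl("^pause", s$label) && !grepl("^pause", last$label) &&
      s$n5 == last$n5 && s$n3 == last$n3 && is.finite(last$duration) &&
      is.finite(s$duration)
    if (mergeable) {
      last$duration <- last$duration + s$duration
      last$label <- paste(last$label, s$label, sep = " + ")
      out[[length(out)]] <- last
    } else out[[length(out) + 1L]] <- s
  }
  out
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule (", attr(x, "model"), " model, gene '",
      attr(x, "gene_id"), "', speed ",
      if (is.infinite(attr(x, "speed"))) "Inf" else
        paste(attr(x, "speed"), "kb/min"), ")\n", sep = "")
  for (i in seq_along(x)) {
    p <- x[[i]]
    cat(sprintf("  %2d. %-28s T = %-10s n5 = %d, n3 = %d%s\n", i, p$label,
                if (is.infinite(p$duration)) "Inf" else
                  paste0(signif(p$duration, 5), " min"),
                p$n5, p$n3,
                if (length(p$overrides))
                  paste0("  [", paste(names(p$overrides), p$overrides,
                                      sep = "=", collapse = ", "), "]")
                else ""))
  }
  invisible(x)
}
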