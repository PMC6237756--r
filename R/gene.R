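#' Gene structure from exon and intron lengths
#'
#' A gene with `N` introns is described entirely by its ordered exon and intron
#' lengths (5' to 3'): `N + 1` exons interleaved with `N` introns. Lengths are
#' the only genomic feature the splicing model uses; there is no sequence-level
#' splice-site scoring. A gene with `N` introns has `N - 1` internal exons and
#' therefore `2^(N-1)` possible fully spliced isoforms.
#'
#' @param exons integer vector of exon lengths in nucleotides, 5' to 3'
#'   (length `N + 1`, all >= 1).
#' @param introns integer vector of intron lengths in nucleotides, 5' to 3'
#'   (length `N`, all >= 1).
#' @param gene_id character label.
#' @return An object of class `"gene_structure"`: a list with elements
#'   `gene_id`, `exons`, `introns` and `n_introns`.
#' @examples
#' g <- gene_structure(c(300, 300, 300), c(3000, 3000), "model2i")
#' g
#' @seealso [read_gene_table()], [phase_schedule()], [ctsplice()]
#' @export
gene_structure <- function(exons, introns, gene_id = "gene") {
  exons <- as.numeric(exons)
  introns <- as.numeric(introns)
  if (length(introns) < 1L)
    stop("a gene must have at least one intron", call. = FALSE)
  if (length(exons) != length(introns) + 1L)
    stop("gene '", gene_id, "': expected ", length(introns) + 1L,
         " exons for ", length(introns), " introns, got ", length(exons),
         call. = FALSE)
  if (anyNA(exons) || anyNA(introns) ||
      any(exons < 1) || any(introns < 1))
    stop("gene '", gene_id, "': all exon and intron lengths must be >= 1 nt",
         call. = FALSE)
  structure(
    list(gene_id = as.character(gene_id)[1L],
         exons = exons, introns = introns,
         n_introns = length(introns)),
    class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("Gene structure '", x$gene_id, "': ", x$n_introns, " introns, ",
      x$n_introns + 1L, " exons\n", sep = "")
  cat("  exons  (nt):", paste(x$exons, collapse = ", "), "\n")
  cat("  introns (nt):", paste(x$introns, collapse = ", "), "\n")
  cat("  fully spliced isoforms: 2^", x$n_introns - 1L, " = ",
      2L^(x$n_introns - 1L), "\n", sep = "")
  invisible(x)
}

#' Read a gene table (TSV) or a GTF annotation
#'
#' The TSV dialect has a header line and three columns: `gene_id`,
#' `exon_lengths` (comma-separated nucleotide lengths, 5' to 3') and
#' `intron_lengths`. GTF import uses 1-based inclusive coordinates; introns are
#' inferred as the gaps between a transcript's exons, and exons are ordered 5'
#' to 3' using the strand. GTF import requires the \pkg{rtracklayer} package.
#'
#' @param path path to the file.
#' @param format `"tsv"` (default) or `"gtf"`.
#' @param transcript_id for GTF input, the transcript to use per gene; by
#'   default the transcript with the largest summed exon length is taken.
#' @return A list of [gene_structure()] objects.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\texon_lengths\tintron_lengths",
#'              "g1\t100,50,200\t3000,3000"), tf)
#' read_gene_table(tf)
#' @export
read_gene_table <- function(path, format = c("tsv", "gtf"),
                            transcript_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") read_gene_tsv(path) else read_gene_gtf(path, transcript_id)
}

read_gene_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L)
    stop("empty gene table: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("gene_id", "exon_lengths", "intron_lengths")
  idx <- match(need, header)
  if (anyNA(idx))
    stop("gene table header must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  parse_lens <- function(s, what, line) {
    v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]]))
    if (length(v) == 0L || anyNA(v))
      stop("line ", line, ": cannot parse ", what, " '", s, "'", call. = FALSE)
    v
  }
  out <- vector("list", length(lines) - 1L)
  for (k in seq_along(out)) {
    line <- k + 1L
    fields <- strsplit(lines[line], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < max(idx))
      stop("line ", line, ": expected ", max(idx), " tab-separated fields",
           call. = FALSE)
    ex <- parse_lens(fields[idx[2L]], "exon_lengths", line)
    io <- parse_lens(fields[idx[3L]], "intron_lengths", line)
    out[[k]] <- tryCatch(
      gene_structure(ex, io, fields[idx[1L]]),
      error = function(e) stop("line ", line, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

read_gene_gtf <- function(path, transcript_id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GTF import requires the 'rtracklayer' package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L)
    stop("no exon records in GTF: ", path, call. = FALSE)
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE)
  out <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    if (!is.null(transcript_id)) {
      sub <- sub[sub$transcript_id %in% transcript_id, , drop = FALSE]
      if (nrow(sub) == 0L) next
    } else {
      totals <- tapply(sub$end - sub$start + 1L, sub$transcript_id, sum)
      keep <- names(totals)[which.max(totals)]
      sub <- sub[sub$transcript_id == keep, , drop = FALSE]
    }
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning("GTF transcript for gene '", gid,
              "' has fewer than 2 exons; skipped", call. = FALSE)
      next
    }
    ex <- sub$end - sub$start + 1L
    io <- sub$start[-1L] - sub$end[-nrow(sub)] - 1L
    if (any(io < 1L))
      stop("gene '", gid, "': overlapping or adjacent exons in GTF",
           call. = FALSE)
    if (sub$strand[1L] == "-") {          # order 5' -> 3'
      ex <- rev(ex); io <- rev(io)
    }
    out[[length(out) + 1L]] <- gene_structure(ex, io, gid)
  }
  out
}

#' Write a gene table TSV
#'
#' @param genes a list of [gene_structure()] objects (a single one is
#'   accepted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  if (inherits(genes, "gene_structure")) genes <- list(genes)
  rows <- vapply(genes, function(g)
    paste(g$gene_id,
          paste(g$exons, collapse = ","),
          paste(g$introns, collapse = ","), sep = "\t"), character(1L))
  writeLines(c("gene_id\texon_lengths\tintron_lengths", rows), path)
  invisible(path)
}
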