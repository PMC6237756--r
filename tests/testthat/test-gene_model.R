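test_that("gene_structure validates its invariants", {
  g <- gene_structure(c(100, 50, 200), c(3000, 3000), "g1")
  expect_s3_class(g, "gene_structure")
  expect_equal(g$n_introns, 2L)
  expect_error(gene_structure(c(100, 50, 200), c(1, 2, 3)), "exons")
  expect_error(gene_structure(c(100, 0, 200), c(10, 10)), ">= 1 nt")
  expect_error(gene_structure(c(100, 200), numeric(0)), "at least one intron")
})

test_that("TSV gene tables parse, reject malformed rows, and round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\texon_lengths\tintron_lengths",
               "g1\t100,50,200\t3000,3000"), tf)
  genes <- read_gene_table(tf)
  expect_length(genes, 1L)
  expect_equal(genes[[1L]]$exons, c(100, 50, 200))
  expect_equal(genes[[1L]]$introns, c(3000, 3000))

  writeLines(c("gene_id\texon_lengths\tintron_lengths",
               "bad\t100,50,200\t1,2,3"), tf)
  expect_error(read_gene_table(tf), "line 2")

  writeLines(c("gene_id\texon_lengths\tintron_lengths",
               "bad\t100,xx\t30"), tf)
  expect_error(read_gene_table(tf), "line 2")

  cohort <- sample_genes(species_length_profile("fly-like"), 5, 3, seed = 4)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(cohort, out)
  back <- read_gene_table(out)
  for (k in seq_along(cohort)) {
    expect_equal(back[[k]]$gene_id, cohort[[k]]$gene_id)
    expect_equal(back[[k]]$exons, cohort[[k]]$exons)
    expect_equal(back[[k]]$introns, cohort[[k]]$introns)
  }
})

test_that("GTF import infers intron lengths from exon gaps", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "gA"; transcript_id "tA";'
  writeLines(c(
    paste("chr1", "src", "exon", 1, 100, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 201, 260, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 401, 600, ".", "+", ".", attrs, sep = "\t")),
    gtf)
  genes <- read_gene_table(gtf, format = "gtf")
  expect_length(genes, 1L)
  expect_equal(genes[[1L]]$exons, c(100, 60, 200))
  expect_equal(genes[[1L]]$introns, c(100, 140))
})

test_that("minus-strand GTF transcripts are ordered 5' to 3' and single-exon ones skipped", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  a1 <- 'gene_id "gB"; transcript_id "tB";'
  a2 <- 'gene_id "gC"; transcript_id "tC";'
  writeLines(c(
    paste("chr1", "src", "exon", 1, 100, ".", "-", ".", a1, sep = "\t"),
    paste("chr1", "src", "exon", 201, 260, ".", "-", ".", a1, sep = "\t"),
    paste("chr1", "src", "exon", 5, 50, ".", "+", ".", a2, sep = "\t")),
    gtf)
  expect_warning(genes <- read_gene_table(gtf, format = "gtf"),
                 "fewer than 2 exons")
  expect_length(genes, 1L)
  expect_equal(genes[[1L]]$exons, c(60, 100))   # downstream exon first on -
  expect_equal(genes[[1L]]$introns, 100)
})

test_that("phase durations follow element lengths over speed", {
  g <- two_intron_gene()
  sch <- phase_schedule(g, elongation_profile(3))
  dur <- vapply(sch, `[[`, numeric(1L), "duration")
  expect_equal(dur[1L], (300 + 3000) / 3000)    # T1 = 1.1 min
  expect_equal(dur[2L], 300 / 3000)             # T2: final exon
  expect_true(is.infinite(dur[length(dur)]))
  # total finite time = gene length downstream of intron 1's 3' end / speed
  expect_equal(sum(dur[is.finite(dur)]), (300 + 3000 + 300) / 3000)

  # doubling speed halves every finite duration
  dur2 <- vapply(phase_schedule(g, elongation_profile(6)), `[[`,
                 numeric(1L), "duration")
  expect_equal(dur2[is.finite(dur2)], dur[is.finite(dur)] / 2)

  # instantaneous elongation: all finite durations zero
  dur_inf <- vapply(phase_schedule(g, elongation_profile(Inf)), `[[`,
                    numeric(1L), "duration")
  expect_true(all(dur_inf[is.finite(dur_inf)] == 0))
})

test_that("synthesized-site sets grow monotonically and durations are non-negative", {
  for (model in c("simple", "full")) {
    sch <- phase_schedule(three_intron_gene(), elongation_profile(2), model)
    n5 <- vapply(sch, `[[`, integer(1L), "n5")
    n3 <- vapply(sch, `[[`, integer(1L), "n3")
    dur <- vapply(sch, `[[`, numeric(1L), "duration")
    expect_true(all(diff(n5) >= 0) && all(diff(n3) >= 0))
    expect_true(all(dur >= 0))
    expect_true(all(n5 >= n3))    # a 5'ss is synthesized before its 3'ss
  }
})

test_that("full-model schedule opens with the intron-1 sub-phase (only 5'ss 1 present)", {
  sch <- phase_schedule(two_intron_gene(), elongation_profile(3), "full")
  expect_equal(sch[[1L]]$n5, 1L)
  expect_equal(sch[[1L]]$n3, 0L)
  expect_equal(sch[[1L]]$duration, 3000 / 3000)
})

test_that("pauses insert zero-elongation phases carrying their overrides", {
  p <- pol_pause("3ss", 1, 1 / 60, c(k3.1 = 20))
  sch <- phase_schedule(two_intron_gene(), elongation_profile(3, list(p)),
                        "full")
  labs <- vapply(sch, `[[`, character(1L), "label")
  k <- grep("^pause", labs)
  expect_length(k, 1L)
  expect_equal(sch[[k]]$duration, 1 / 60)
  expect_equal(sch[[k]]$overrides, c(k3.1 = 20))
  expect_equal(sch[[k]]$n3, 1L)           # inserted right after 3'ss(1)
  # pause does not change total elongation time outside itself
  base <- phase_schedule(two_intron_gene(), elongation_profile(3), "full")
  expect_equal(sum(vapply(sch, `[[`, numeric(1L), "duration")[
    is.finite(vapply(sch, `[[`, numeric(1L), "duration"))]),
    sum(vapply(base, `[[`, numeric(1L), "duration")[
      is.finite(vapply(base, `[[`, numeric(1L), "duration"))]) + 1 / 60)

  expect_error(phase_schedule(two_intron_gene(),
                              elongation_profile(3, list(pol_pause("3ss", 5, 1)))),
               "outside")
  expect_error(phase_schedule(two_intron_gene(),
                              elongation_profile(3, list(pol_pause("5ss", 1, 1))),
                              "simple"),
               "full model")
})
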