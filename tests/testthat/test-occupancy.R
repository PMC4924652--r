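test_that("occupancy profile obeys the fpm formula and normalization", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 400L)
  one <- fragment_table("chr1", 100L, 250L)
  prof <- occupancy_profile(one, regions, total = 1L)
  covered <- prof[prof$score > 0, ]
  expect_equal(covered$start, 100L)
  expect_equal(covered$end, 250L)
  expect_equal(covered$score, 1e6)
  ## two identical fragments at total 2 give the same profile
  two <- rbind(one, one)
  prof2 <- occupancy_profile(two, regions, total = 2L)
  expect_equal(prof2, prof, ignore_attr = TRUE)
  expect_error(occupancy_profile(one[0, ], regions), "total")
})

test_that("occupancy profile equals brute-force coverage counting", {
  set.seed(11)
  n <- 500L
  start <- sample.int(3000L, n, TRUE)
  fr <- fragment_table("chr1", start, start + sample(50:200, n, TRUE))
  regions <- data.frame(chrom = "chr1", start = c(100L, 1500L),
                        end = c(1200L, 2600L))
  prof <- occupancy_profile(fr, regions)
  ## expand runs to per-bp and compare to the nested-loop oracle
  for (j in sample(nrow(prof), 25L)) {
    p <- prof$start[j]
    expect_equal(prof$score[j],
                 oracle_coverage(fr, "chr1", p) * 1e6 / n)
  }
  ## linearity in the fragment multiset before normalization
  prof_a <- occupancy_profile(fr[1:250, ], regions, total = 1)
  prof_b <- occupancy_profile(fr[251:500, ], regions, total = 1)
  bp_val <- function(pr, p) {
    hit <- pr$start <= p & pr$end > p
    if (any(hit)) pr$score[hit] else 0
  }
  for (p in c(150L, 600L, 1100L, 2000L))
    expect_equal(bp_val(prof, p) * n,
                 bp_val(prof_a, p) + bp_val(prof_b, p))
})

test_that("dyad track counts midpoints in stepped windows", {
  fr <- fragment_table("chr1", 100L, 250L)  # midpoint 175
  tr <- dyad_track(fr, window = 100L, step = 10L)
  hit <- tr$start[tr$count == 1L]
  expect_equal(hit, seq(80L, 170L, by = 10L))
  expect_true(all(tr$count[!tr$start %in% hit] == 0L))
  ## empty input
  expect_equal(nrow(dyad_track(fr[0, ])), 0L)
  ## conservation over a non-overlapping tiling, and the window oracle
  set.seed(3)
  start <- sample.int(5000L, 300L)
  fr2 <- fragment_table("chr1", start, start + 150L)
  tiling <- dyad_track(fr2, window = 50L, step = 50L)
  expect_equal(sum(tiling$count), nrow(fr2))
  tr2 <- dyad_track(fr2, window = 100L, step = 10L)
  expect_equal(tr2$count,
               as.integer(oracle_window_counts(fr2$midpoint, tr2$start, 100L)))
})

test_that("tss_matrix orients rows by strand and zero-fills clipped windows", {
  fr <- fragment_table("chr1", c(900L, 1200L), c(1050L, 1350L))
  tss <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                    tss = 1000L, strand = c("+", "-"))
  mat <- tss_matrix(fr, tss, flank = 300L, grid = "dyad", window = 100L,
                    step = 10L, normalize = FALSE)
  ## minus-strand row is the reverse of the plus-strand row of the same locus
  expect_equal(unname(mat["minus", ]), unname(rev(mat["plus", ])))
  ## per-bp grid: row values equal strand-oriented coverage lookups
  bp <- tss_matrix(fr, tss, flank = 100L, grid = "bp", normalize = FALSE)
  offs <- positions(bp)
  expect_equal(unname(bp["plus", ]),
               oracle_coverage(fr, "chr1", 1000L + offs))
  expect_equal(unname(bp["minus", ]),
               oracle_coverage(fr, "chr1", 1000L - offs))
  ## clipped window detection
  mat2 <- tss_matrix(fr, tss, flank = 1100L, chrom_sizes = c(chr1 = 2000L))
  expect_setequal(attr(mat2, "clipped_genes"), c("plus", "minus"))
})

test_that("cohort-average profile shows the planted NDR at the TSS", {
  st <- small_study()
  avg <- average_profile(st$mat_normal)
  ## the synthetic world is a 2 kb island, so signal decays at the window
  ## edges; the NDR claim concerns the promoter-proximal region
  central <- avg[abs(avg$position) <= 500L, ]
  trough <- central$position[which.min(central$mean)]
  ## every template's NDR sits within [-180, 170]; the proximal trough
  ## must fall inside that pooled NDR span
  expect_gte(trough, -180L)
  expect_lte(trough, 170L)
  ## flanking nucleosome peaks rise well above the NDR floor
  expect_gt(max(central$mean), 2 * min(central$mean))
})

test_that("average_profile subsetting recombines to the full mean", {
  st <- small_study()
  m <- st$mat_normal
  genes <- rownames(m)
  sub <- genes[1:15]
  rest <- setdiff(genes, sub)
  a <- average_profile(m, sub)
  b <- average_profile(m, rest)
  full <- average_profile(m)
  expect_equal((a$mean * a$n + b$mean * b$n) / (a$n + b$n), full$mean)
  ## single-gene subset is that row
  one <- average_profile(m, genes[3])
  expect_equal(one$mean, unname(m[genes[3], ]))
  expect_error(average_profile(m, "nonexistent"), "absent")
})
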