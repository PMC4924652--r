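test_that("shuffled peaks preserve lengths and respect capture space", {
  st <- small_study()
  sh <- shuffle_peaks(st$peaks, st$ann$capture, n_iter = 5L, seed = 3L)
  cap <- st$ann$capture
  for (it in 1:5) {
    s <- sh[sh$iteration == it, ]
    expect_equal(sort(s$end - s$start),
                 sort(st$peaks$end - st$peaks$start))
    expect_equal(s$chrom, st$peaks$chrom)
    inside <- vapply(seq_len(nrow(s)), function(i) {
      any(cap$chrom == s$chrom[i] & cap$start <= s$start[i] &
            s$end[i] <= cap$end)
    }, logical(1))
    expect_true(all(inside))
  }
  ## deterministic per seed
  sh2 <- shuffle_peaks(st$peaks, st$ann$capture, n_iter = 5L, seed = 3L)
  expect_identical(sh, sh2)
  ## forced placement: capture region exactly the peak
  pk <- data.frame(chrom = "chr1", start = 100L, end = 300L, name = "p",
                   summit = 200L)
  one <- shuffle_peaks(pk, data.frame(chrom = "chr1", start = 100L,
                                      end = 300L), n_iter = 2L, seed = 1L)
  expect_true(all(one$start == 100L))
  expect_error(shuffle_peaks(pk, data.frame(chrom = "chr1", start = 0L,
                                            end = 100L), n_iter = 1L),
               "longer than every capture region")
})

test_that("shuffled placements are uniform over valid starts", {
  pk <- data.frame(chrom = "chr1", start = 0L, end = 10L, name = "p",
                   summit = 5L)
  cap <- data.frame(chrom = "chr1", start = 0L, end = 109L)  # 100 starts
  sh <- shuffle_peaks(pk, cap, n_iter = 3000L, seed = 11L)
  tab <- tabulate(sh$start + 1L, nbins = 100L)
  gof <- suppressWarnings(chisq.test(tab))
  expect_gt(gof$p.value, 0.01)
})

test_that("enrichment ratio arithmetic and self-null", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 500L),
                        end = c(100L, 600L))
  mk <- function(summits) data.frame(chrom = "chr1", summit = summits,
                                     start = summits - 5L,
                                     end = summits + 5L)
  observed <- mk(c(10L, 50L, 550L, 900L))  # 3 summits inside
  shuffled <- list(mk(c(10L, 900L, 901L, 902L)),    # 1 inside
                   mk(c(20L, 30L, 903L, 904L)))     # 2 inside
  er <- enrichment_ratio(regions, observed, shuffled)
  expect_equal(er$observed_count, 3L)
  expect_equal(er$shuffled_mean, 1.5)
  expect_equal(er$ratio, 2)
  expect_error(enrichment_ratio(regions[0, ], observed, shuffled), "empty")
  expect_error(enrichment_ratio(regions, observed, shuffled[1L]),
               ">= 2 shuffle")
  ## using one shuffled iteration as "observed" centers the ratio near 1
  st <- small_study()
  sh <- shuffle_peaks(st$peaks, st$ann$capture, n_iter = 60L, seed = 5L)
  iters <- split(sh, sh$iteration)
  regs <- data.frame(chrom = st$ann$capture$chrom,
                     start = st$ann$capture$start,
                     end = st$ann$capture$start + 400L)
  er2 <- enrichment_ratio(regs, iters[[1L]], iters[-1L])
  expect_gt(er2$ratio, 0.5)
  expect_lt(er2$ratio, 2)
  expect_true(er2$inside)
})

test_that("aggregate footprint matches the double-loop oracle", {
  set.seed(17)
  start <- sample.int(4000L, 400L)
  fr <- fragment_table("chr1", start, start + sample(60:124, 400L, TRUE))
  peaks <- data.frame(chrom = "chr1",
                      summit = as.integer(c(500, 1500, 2500, 3500)))
  fp <- aggregate_footprint(fr, peaks, flank = 300L, total = 400L)
  want <- oracle_footprint(fr$midpoint, peaks$summit, 300L)
  expect_equal(fp$count, want$count)
  expect_equal(fp$signal, want$count * 1e6 / 400)
  ## conservation of (fragment, peak) hits
  expect_equal(sum(fp$count),
               sum(outer(fr$midpoint, peaks$summit,
                         function(m, s) abs(m - s) <= 300L)))
  ## translation covariance: shifting peaks by +7 shifts the profile by -7
  fp7 <- aggregate_footprint(fr, transform(peaks, summit = summit + 7L),
                             flank = 300L, total = 400L)
  off <- fp$offset >= -293L & fp$offset <= 293L
  expect_equal(fp7$count[fp7$offset >= -300L & fp7$offset <= 286L],
               fp$count[fp$offset >= -293L & fp$offset <= 293L])
  ## single spike at offset 0
  spike <- aggregate_footprint(fragment_table("chr1", 960L, 1040L),
                               data.frame(chrom = "chr1", summit = 1000L),
                               flank = 50L)
  expect_equal(spike$count[spike$offset == 0L], 1L)
  expect_equal(sum(spike$count), 1L)
  expect_error(aggregate_footprint(fr[0, ], peaks), "no fragments")
})

test_that("binding change recovers the percent-change convention", {
  mk_fp <- function(core_signal) {
    structure(data.frame(offset = -200:200, count = 0L,
                         signal = c(rep(0, 150),
                                    rep(core_signal / 101, 101),
                                    rep(0, 150))),
              n_peaks = 10L, total = 1000L,
              class = c("aggregate_footprint", "data.frame"))
  }
  bc <- binding_change(mk_fp(100), mk_fp(87), core_halfwidth = 100L)
  expect_equal(bc$percent_change, -13)
  expect_equal(binding_change(mk_fp(50), mk_fp(50))$percent_change, 0)
  expect_error(binding_change(mk_fp(0), mk_fp(10)), "zero")
})

test_that("planted binding multipliers are recovered at TF footprints", {
  st <- small_study()
  tot_n <- nrow(st$normal); tot_t <- nrow(st$tumor)
  sub_n <- partition_by_size(st$normal, "subnucleosomal")
  sub_t <- partition_by_size(st$tumor, "subnucleosomal")
  nuc_n <- partition_by_size(st$normal, "nucleosomal")
  for (f in unique(st$peaks$factor)) {
    pk <- st$peaks[st$peaks$factor == f, ]
    fp_n <- aggregate_footprint(sub_n, pk, total = tot_n)
    fp_t <- aggregate_footprint(sub_t, pk, total = tot_t)
    bc <- binding_change(fp_n, fp_t)
    planted <- 100 * (pk$tumor_mult[1L] - 1)
    ## 20 peaks x ~10 fragments in the small study: generous tolerance
    expect_lt(abs(bc$percent_change - planted), 15)
    ## nucleosome-sized fragments are locally depleted at summits (NDR)
    fp_nuc <- aggregate_footprint(nuc_n, pk, total = tot_n)
    core <- abs(fp_nuc$offset) <= 50L
    flank_band <- abs(fp_nuc$offset) >= 350L
    expect_lt(mean(fp_nuc$signal[core]), mean(fp_nuc$signal[flank_band]))
  }
})
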