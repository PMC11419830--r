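test_that("expansion size is the observed excess over the corrected reference distance", {
  loc <- ctg18_locus()
  map <- ctg18_marker_map()
  # a reference-identical molecule: markers at their hg38 spacings
  off <- 55584360 - 10000
  mol <- molecule(1L, 80000, c(55584360, 55594648, 55595438) - off + 1)
  aln <- structure(list(molecule_id = 1L, contig = "chr18", orientation = "+",
                        pairs = data.frame(ref_id = c(10414L, 10415L, 10416L),
                                           qry_site = 1:3),
                        score = 15, confidence = 15),
                   class = "ogm_alignment")
  call <- size_molecule(aln, mol, loc)
  expect_equal(call$observed_distance, 10683)  # averaged marker pair
  expect_equal(call$expansion_size, 10683 - 10611)
  expect_equal(call$repeat_estimate, 24)       # the reference's own tract

  # the F35T modal cluster: observed 24,111 bp -> 13,500 bp -> 4500 repeats
  mol2 <- molecule(2L, 80000, c(10000, 10000 + 24111))
  aln2 <- structure(list(molecule_id = 2L, contig = "chr18", orientation = "+",
                         pairs = data.frame(ref_id = c(10414L, 10415L),
                                            qry_site = 1:2),
                         score = 10, confidence = 10),
                    class = "ogm_alignment")
  call2 <- size_molecule(aln2, mol2, loc)
  expect_equal(call2$expansion_size, 13500)
  expect_equal(to_repeats(call2$expansion_size, 3, "exact"), 4500)

  # missing markers must be caught
  aln3 <- aln2
  aln3$pairs <- data.frame(ref_id = 10414L, qry_site = 1L)
  expect_error(size_molecule(aln3, mol2, loc), "both locus markers")
})

test_that("repeat conversion supports exact, floor, and nearest-hundred reporting", {
  expect_equal(to_repeats(13500, 3, "exact"), 4500)
  expect_equal(to_repeats(500, 3, "floor"), 166)
  expect_equal(to_repeats(16803, 3, "nearest_hundred"), 5600)
  expect_equal(to_repeats(35561, 3, "nearest_hundred"), 11900)
  expect_equal(to_repeats(-300, 3, "exact"), -100)
  expect_error(to_repeats(100, 0), "unit > 0")
})

test_that("histograms use half-open 200 bp bins and conserve counts", {
  h <- histogram_sizes(c(0, 199, 200), 200)
  expect_equal(h$count[h$bin_start == 0], 2)
  expect_equal(h$count[h$bin_start == 200], 1)
  expect_equal(nrow(histogram_sizes(numeric(0))), 0)

  set.seed(17)
  for (rep in 1:10) {
    sizes <- round(rnorm(sample(5:300, 1), 500, 2000))
    h <- histogram_sizes(sizes, 200)
    expect_equal(sum(h$count), length(sizes))
    oracle <- naive_bins(sizes, 200)
    expect_equal(h$count[match(as.numeric(names(oracle)) * 200, h$bin_start)],
                 as.vector(oracle))
  }
})

test_that("sample summaries pool both alleles unphased", {
  calls <- data.frame(molecule_id = 1:2, observed_distance = c(10611, 24111),
                      expansion_size = c(0, 13500),
                      repeat_estimate = c(0, 4500),
                      downstream_rep = "both")
  s <- summarize_sample(calls, "demo")
  expect_equal(s$mean_size, 6750)
  expect_equal(s$max_size, 13500)
  expect_equal(s$n_molecules, 2)
  expect_equal(s$expanded_fraction, 0.5)
  expect_equal(sum(s$histogram$count), 2)

  s0 <- summarize_sample(calls[0, ], "empty")
  expect_true(s0$empty)
  expect_equal(s0$n_molecules, 0)
  expect_true(is.na(s0$mean_size))
})

test_that("non-expanded samples carry no true expanded molecules; rare misalignment artifacts are non-clustering", {
  reg <- shared_region()
  prof <- tissue_profile("ctrl", allele_model(11), allele_model(24))
  sim <- simulate_molecules(prof, reg, 800, seed = 19)
  res <- size_pipeline(sim, sample_id = "ctrl")
  expect_gt(res$summary$n_molecules, 30)
  # truth-table oracle: every tract <= 24 repeats, so no true molecule
  # exceeds the 2000 bp expanded threshold
  expect_true(all(3 * sim$truth$truth_repeats <= 2000))
  # the pipeline may add isolated misalignment artifacts (at most ~1-2%)
  expect_lte(res$summary$expanded_fraction, 0.02)
  expect_equal(sum(res$summary$histogram$count), res$summary$n_molecules)
  # artifacts are single non-clustering molecules: the optional
  # cluster-support filter removes them entirely
  filt <- summarize_sample(res$calls, "ctrl", min_cluster_support = 3)
  expect_equal(filt$expanded_fraction, 0)
})

test_that("raising every tract by 100 repeats raises the mean size by ~300 bp", {
  reg <- shared_region()
  base <- tissue_profile("b", allele_model(50), allele_model(50))
  up <- tissue_profile("u", allele_model(150), allele_model(150))
  r1 <- size_pipeline(simulate_molecules(base, reg, 700, seed = 23,
                                         span_only = TRUE))
  r2 <- size_pipeline(simulate_molecules(up, reg, 700, seed = 24,
                                         span_only = TRUE))
  shift <- r2$summary$mean_size - r1$summary$mean_size
  se <- sqrt(sd(r1$calls$expansion_size)^2 / r1$summary$n_molecules +
             sd(r2$calls$expansion_size)^2 / r2$summary$n_molecules)
  expect_lt(abs(shift - 300), 4 * se)
})
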