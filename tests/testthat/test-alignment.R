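make_ref <- function(pos) label_map("ref", max(pos) + 1000, pos)

test_that("a noiseless copy of the reference aligns as the identity pairing", {
  pos <- c(1000, 5000, 12000, 20000, 31000, 45000)
  map <- make_ref(pos)
  mol <- molecule(1L, 50000, pos)
  p <- align_penalties(min_flank = 3, free_gap = NULL)
  a <- align_molecule(mol, map, p)
  expect_equal(a$pairs$ref_id, 1:6)
  expect_equal(a$pairs$qry_site, 1:6)
  expect_equal(a$orientation, "+")
  expect_equal(a$score, 6 * p$match_score)
})

test_that("deleting one molecule label costs exactly one match plus one reference miss", {
  pos <- c(1000, 5000, 12000, 20000, 31000, 45000)
  map <- make_ref(pos)
  p <- align_penalties()
  full <- align_molecule(molecule(1L, 50000, pos), map, p)
  pruned <- align_molecule(molecule(1L, 50000, pos[-3]), map, p)
  expect_equal(nrow(pruned$pairs), 5)
  expect_equal(full$score - pruned$score, p$match_score + p$miss_ref)
  # a terminal label costs only its forgone match (free ends)
  tip <- align_molecule(molecule(1L, 50000, pos[-6]), map, p)
  expect_equal(full$score - tip$score, p$match_score)
})

test_that("the DP optimum equals exhaustive search over monotone pairings", {
  set.seed(21)
  p <- align_penalties(size_cost = 1e-5, min_flank = 1, max_skip = 7)
  for (rep in 1:25) {
    nr <- sample(4:8, 1); nq <- sample(4:7, 1)
    ref <- sort(sample.int(60000, nr))
    ref <- ref[c(TRUE, diff(ref) > 100)]
    qry <- sort(round(runif(nq, 1, 55000)))
    qry <- qry[c(TRUE, diff(qry) > 100)]
    if (length(qry) < 2 || length(ref) < 2) next
    got <- .dp_align(as.numeric(ref), as.numeric(qry),
                     p$match_score, p$miss_ref, p$miss_qry, p$size_cost,
                     0, 0, FALSE, p$max_skip)
    expect_equal(got$score, best_pairing_score(ref, qry, p), tolerance = 1e-9)
  }
  # with a declared free interval on the reference
  for (rep in 1:10) {
    ref <- sort(sample.int(60000, 6))
    qry <- sort(round(runif(6, 1, 70000)))
    if (any(diff(ref) < 100) || any(diff(qry) < 100)) next
    pf <- align_penalties(size_cost = 1e-5, min_flank = 1, max_skip = 7,
                          free_gap = ref[c(3, 4)])
    got <- .dp_align(as.numeric(ref), as.numeric(qry),
                     pf$match_score, pf$miss_ref, pf$miss_qry, pf$size_cost,
                     pf$free_gap[1], pf$free_gap[2], TRUE, pf$max_skip)
    expect_equal(got$score, best_pairing_score(ref, qry, pf), tolerance = 1e-9)
  }
})

test_that("alignment score is invariant under molecule reversal", {
  set.seed(31)
  map <- make_ref(sort(sample.int(2e5, 12)))
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    len <- 2.2e5
    qry <- sort(round(runif(n, 1, len)))
    if (any(diff(qry) < 50)) next
    fwd <- align_molecule(molecule(1L, len, qry), map,
                          align_penalties(min_flank = 1))
    rev <- align_molecule(molecule(1L, len, sort(len - qry + 1)), map,
                          align_penalties(min_flank = 1))
    expect_equal(rev$score, fwd$score, tolerance = 1e-9)
  }
})

test_that("alignments with too few labels or flank support are rejected", {
  map <- make_ref(c(1000, 5000, 12000, 20000, 31000, 45000))
  expect_null(align_molecule(molecule(1L, 50000, c(1000, 5000)), map))
  p <- align_penalties(free_gap = c(12000, 20000), min_flank = 3)
  # all labels left of the free interval: no downstream flank support
  expect_null(align_molecule(molecule(1L, 50000, c(1000, 3000, 5000, 7000, 9000)),
                             map, p))
})

test_that("spanning selection keeps only alignments covering both locus markers", {
  fix <- shared_noiseless_f35t()
  sim <- fix$sim
  loc <- sim$region$locus
  sp <- fix$res$spanning
  up <- loc$upstream[["id"]]; dn <- loc$downstream[["id"]]
  cp <- loc$companion[["id"]]
  for (a in sp) {
    expect_true(up %in% a$pairs$ref_id)
    expect_true(any(c(dn, cp) %in% a$pairs$ref_id))
  }
  # truth-table oracle under zero noise: exactly the alignable spanning set
  expect_setequal(vapply(sp, `[[`, integer(1), "molecule_id"),
                  sim$truth$molecule_id[sim$truth$spanning])
  # idempotence
  again <- select_spanning(sp, loc)
  expect_equal(length(again), length(sp))
  expect_equal(vapply(again, `[[`, integer(1), "molecule_id"),
               vapply(sp, `[[`, integer(1), "molecule_id"))
})

test_that("XMAP round trip preserves alignments and orientation conventions", {
  map <- make_ref(c(1000, 5000, 12000, 20000, 31000, 45000))
  mols <- list(molecule(3L, 50000, c(1000, 5000, 12000, 20000, 31000)),
               molecule(4L, 50000, sort(50000 - c(1000, 5000, 12000, 20000, 31000) + 1)))
  aln <- align_molecules(mols, map, align_penalties(min_flank = 1))
  expect_length(aln, 2)
  expect_equal(aln[[2]]$orientation, "-")
  # reversed-orientation pairs: qry sites decrease as ref ids increase
  expect_true(all(diff(aln[[2]]$pairs$qry_site) < 0))

  path <- withr::local_tempfile(fileext = ".xmap")
  write_xmap(aln, path, map = map, molecules = mols)
  back <- read_xmap(path)
  expect_length(back, 2)
  for (k in 1:2) {
    expect_equal(back[[k]]$molecule_id, aln[[k]]$molecule_id)
    expect_equal(back[[k]]$orientation, aln[[k]]$orientation)
    expect_equal(back[[k]]$pairs, aln[[k]]$pairs)
    expect_equal(back[[k]]$confidence, aln[[k]]$confidence, tolerance = 0.01)
  }
})

test_that("minimal and malformed XMAP inputs are handled", {
  path <- withr::local_tempfile(fileext = ".xmap")
  writeLines(c("# XMAP File Version:\t0.2",
               paste0("#h\t", paste(c("XmapEntryID", "QryContigID", "RefContigID",
                                      "QryStartPos", "QryEndPos", "RefStartPos",
                                      "RefEndPos", "Orientation", "Confidence",
                                      "HitEnum", "QryLen", "RefLen", "LabelChannel",
                                      "Alignment"), collapse = "\t")),
               "1\t5\t1\t0\t0\t0\t0\t+\t12.0\t2M\t0\t0\t1\t(1,1)(2,2)"), path)
  a <- read_xmap(path)
  expect_length(a, 1)
  expect_equal(a[[1]]$pairs$ref_id, 1:2)
  expect_equal(a[[1]]$molecule_id, 5L)

  writeLines(c("# XMAP File Version:\t0.2",
               "#h\tXmapEntryID\tQryContigID",
               "1\t5"), path)
  expect_error(read_xmap(path), "Alignment")
})
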