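#' Allele mosaicism models
#'
#' An allele is described by its progenitor (inherited) repeat count and a
#' somatic mosaicism law for the tract lengths actually present across
#' cells:
#' * `"point"` — no somatic variation; every molecule carries the
#'   progenitor tract.
#' * `"truncnorm"` — normal around the progenitor with standard deviation
#'   `sd` repeats, truncated at 0 (low-instability tissues such as blood
#'   leukocytes).
#' * `"lognormal"` — log-normal with modal tract `mode` repeats and
#'   log-scale `sigma` (extreme-instability tissues such as diseased
#'   corneal endothelium, where tracts span thousands of repeats).
#'
#' @param progenitor_repeats Inherited repeat count (>= 0).
#' @param mosaicism One of `"point"`, `"truncnorm"`, `"lognormal"`.
#' @param sd Truncated-normal spread, in repeats.
#' @param mode Log-normal modal repeat count (defaults to
#'   `progenitor_repeats`).
#' @param sigma Log-normal log-scale spread.
#' @return An object of class `ogm_allele`.
#' @export
allele_model <- function(progenitor_repeats,
                         mosaicism = c("point", "truncnorm", "lognormal"),
                         sd = 0, mode = NULL, sigma = 0) {
  mosaicism <- match.arg(mosaicism)
  stopifnot(progenitor_repeats >= 0, sd >= 0, sigma >= 0)
  structure(list(progenitor_repeats = progenitor_repeats,
                 mosaicism = mosaicism, sd = sd,
                 mode = if (is.null(mode)) progenitor_repeats else mode,
                 sigma = sigma),
            class = "ogm_allele")
}

#' Draw somatic tract lengths from an allele model
#'
#' @param allele An `ogm_allele`.
#' @param n Number of draws.
#' @return Integer repeat counts, all >= 0. Uses the current RNG state;
#'   `set.seed()` upstream for reproducibility.
#' @export
sample_tract <- function(allele, n = 1) {
  stopifnot(inherits(allele, "ogm_allele"))
  out <- switch(allele$mosaicism,
    point = rep(allele$progenitor_repeats, n),
    truncnorm = {
      x <- stats::rnorm(n, allele$progenitor_repeats, allele$sd)
      while (any(x < 0))   # resample below the 0-repeat truncation bound
        x[x < 0] <- stats::rnorm(sum(x < 0), allele$progenitor_repeats, allele$sd)
      x
    },
    lognormal = {
      # mode of lognormal(mu, sigma) is exp(mu - sigma^2)
      mu <- log(allele$mode) + allele$sigma^2
      stats::rlnorm(n, mu, allele$sigma)
    })
  as.integer(round_half_up(out))
}

#' Diploid tissue profiles
#'
#' Exactly two alleles (diploid, unphased downstream): molecules are drawn
#' from either with equal probability.
#'
#' @param name Profile name.
#' @param allele_a,allele_b `ogm_allele` models.
#' @return An object of class `ogm_tissue_profile`.
#' @export
tissue_profile <- function(name, allele_a, allele_b) {
  stopifnot(inherits(allele_a, "ogm_allele"), inherits(allele_b, "ogm_allele"))
  structure(list(name = name, allele_a = allele_a, allele_b = allele_b),
            class = "ogm_tissue_profile")
}

#' Built-in tissue profiles
#'
#' `leukocyte_profile()`: a non-expanded short allele plus an expanded
#' allele with low somatic instability, modelled as a truncated normal whose
#' spread grows exponentially with the progenitor size
#' (`sd = sd0 * exp(k * progenitor)` repeats). `cec_profile()`: corneal
#' endothelium-like extreme instability, a log-normal expanded allele with a
#' modal tract in the thousands of repeats. `f35t_profile()`: the
#' immortalised corneal endothelial line used as positive control —
#' STR-detectable 21-repeat allele plus a tight ~4500-repeat expansion
#' (13,500 bp).
#'
#' @param short Non-expanded allele repeat count.
#' @param progenitor Expanded-allele progenitor repeat count.
#' @param sd0,k Instability scaling of the leukocyte-like spread.
#' @param mode Modal somatic tract of the CEC-like expanded allele
#'   (repeats).
#' @param sigma Log-scale spread of the CEC-like expanded allele.
#' @return An `ogm_tissue_profile`.
#' @name builtin_profiles
NULL

#' @rdname builtin_profiles
#' @export
leukocyte_profile <- function(short = 11, progenitor = 90, sd0 = 1, k = 0.025) {
  tissue_profile("leukocyte-like",
                 allele_model(short, "point"),
                 allele_model(progenitor, "truncnorm",
                              sd = sd0 * exp(k * progenitor)))
}

#' @rdname builtin_profiles
#' @export
cec_profile <- function(short = 11, mode = 4500, sigma = 0.25) {
  tissue_profile("CEC-like",
                 allele_model(short, "point"),
                 allele_model(50, "lognormal", mode = mode, sigma = sigma))
}

#' @rdname builtin_profiles
#' @export
fibroblast_profile <- function(short = 11, progenitor = 90, sd0 = 1, k = 0.025) {
  # dermal fibroblasts show leukocyte-like low instability
  p <- leukocyte_profile(short, progenitor, sd0, k)
  p$name <- "fibroblast-like"
  p
}

#' @rdname builtin_profiles
#' @export
f35t_profile <- function() {
  tissue_profile("F35T-like",
                 allele_model(21, "point"),
                 allele_model(50, "lognormal", mode = 4500, sigma = 0.02))
}

#' Assay noise model
#'
#' @param sizing_sd_fraction Gaussian interval-sizing noise as a fraction of
#'   the interval length.
#' @param sizing_sd_floor Lower bound on the interval-sizing SD, in bp (the
#'   assay's ~±500 bp sizing floor corresponds to a ~250 bp SD).
#' @param label_fn_rate Per-label dropout probability.
#' @param label_fp_rate Spurious labels per 100 kb of molecule.
#' @param resolution_limit Molecule labels closer than this collapse to a
#'   single detected site, the survivor chosen uniformly at random.
#' @param detection_floor Reporting floor in bp: expansion sizes within
#'   ±`detection_floor` cannot be sized with confidence (annotated, not
#'   filtered).
#' @return An object of class `ogm_noise`.
#' @export
noise_model <- function(sizing_sd_fraction = 0.02, sizing_sd_floor = 250,
                        label_fn_rate = 0.10, label_fp_rate = 0.8,
                        resolution_limit = 1000, detection_floor = 500) {
  stopifnot(label_fn_rate >= 0, label_fn_rate <= 1, label_fp_rate >= 0,
            sizing_sd_fraction >= 0, sizing_sd_floor >= 0)
  structure(list(sizing_sd_fraction = sizing_sd_fraction,
                 sizing_sd_floor = sizing_sd_floor,
                 label_fn_rate = label_fn_rate,
                 label_fp_rate = label_fp_rate,
                 resolution_limit = resolution_limit,
                 detection_floor = detection_floor),
            class = "ogm_noise")
}

#' @rdname noise_model
#' @export
noise_model_off <- function() {
  noise_model(sizing_sd_fraction = 0, sizing_sd_floor = 0,
              label_fn_rate = 0, label_fp_rate = 0, resolution_limit = 0,
              detection_floor = 500)
}

#' Synthetic locus region: a 1 Mb label map around a CTG18.1-like repeat
#'
#' Emulates the chr18 neighbourhood of CTG18.1 at desk scale: background
#' label sites are drawn from a hard-core renewal process (minimum spacing
#' `min_gap`, density `density` labels/100 kb), and the three locus markers
#' are placed at their true relative offsets — upstream marker at
#' `locus_offset`, downstream 10,288 bp later, companion a further 790 bp
#' (sub-resolution). The reference repeat tract (24 x 3 bp) sits between the
#' upstream and downstream markers. No background label falls within the
#' resolution limit of the markers.
#'
#' @param region_length Region size in bp.
#' @param density Background label density per 100 kb (chosen so molecules
#'   land in the 14–17 labels/100 kb QC window after label dropout and
#'   spurious labels at default noise).
#' @param min_gap Hard-core minimum spacing between background labels, bp.
#' @param locus_offset Position of the upstream marker within the region.
#' @param seed RNG seed for the background label draw.
#' @return An object of class `ogm_region`: list with the `ogm_labelmap`
#'   (`map`), the `ogm_locus` (`locus`), and the reference repeat tract
#'   coordinates (`tract_start`, `tract_end`, `ref_tract_len` = 72 bp).
#' @export
simulate_region <- function(region_length = 1e6, density = 16.3,
                            min_gap = 1200, locus_offset = 5e5, seed = 171) {
  up <- locus_offset
  dn <- up + 10288
  cp <- dn + 790
  mean_gap <- 1e5 / density
  stopifnot(mean_gap > min_gap, cp + min_gap < region_length)
  draw_gaps <- function(from, to) {
    pos <- numeric(0); p <- from
    repeat {
      p <- p + min_gap + stats::rexp(1, 1 / (mean_gap - min_gap))
      if (p > to) break
      pos <- c(pos, p)
    }
    round(pos)
  }
  set.seed(seed)
  left <- draw_gaps(0, up - min_gap)
  right <- draw_gaps(cp, region_length)  # resumes >= min_gap past the companion
  pos <- c(left, up, dn, cp, right)
  map <- label_map("chr18_region", region_length, pos)
  up_id <- map$labels$label_id[match(up, map$labels$position)]
  dn_id <- map$labels$label_id[match(dn, map$labels$position)]
  locus <- build_locus(map, up_id, dn_id, ref_repeat_count = 24,
                       repeat_unit_len = 3, name = "CTG18.1")
  structure(list(map = map, locus = locus,
                 tract_start = up + 1796, tract_end = up + 1796 + 71,
                 ref_tract_len = 72L),
            class = "ogm_region")
}

#' Molecule length model
#'
#' Molecule lengths are log-normal, parameterised by the target N50 (the
#' length-weighted median: for lognormal(mu, sigma) the length-weighted law
#' is lognormal(mu + sigma^2, sigma), so N50 = exp(mu + sigma^2)).
#'
#' @param n50 Target N50 in bp (assay QC requires >= 150 kb).
#' @param sdlog Log-scale spread.
#' @export
length_model <- function(n50 = 180000, sdlog = 0.55) {
  list(meanlog = log(n50) - sdlog^2, sdlog = sdlog, n50 = n50)
}

apply_noise <- function(pos, len, noise) {
  # order per the generative contract: dropout, spurious labels, interval
  # sizing noise, then sub-resolution collapse
  if (noise$label_fn_rate > 0 && length(pos) > 0)
    pos <- pos[stats::runif(length(pos)) > noise$label_fn_rate]
  if (noise$label_fp_rate > 0) {
    nfp <- stats::rpois(1, noise$label_fp_rate * len / 1e5)
    if (nfp > 0) pos <- sort(c(pos, stats::runif(nfp, 1, len)))
  }
  if ((noise$sizing_sd_fraction > 0 || noise$sizing_sd_floor > 0) &&
      length(pos) > 1) {
    g <- diff(pos)
    sd <- pmax(noise$sizing_sd_floor, noise$sizing_sd_fraction * g)
    g <- pmax(1, g + stats::rnorm(length(g), 0, sd))
    pos <- pos[1] + c(0, cumsum(g))
  }
  if (noise$resolution_limit > 0 && length(pos) > 1) {
    repeat {
      g <- diff(pos)
      i <- which(g < noise$resolution_limit)
      if (length(i) == 0) break
      i <- i[1]
      drop <- i + stats::rbinom(1, 1, 0.5)  # survivor uniform between the two
      pos <- pos[-drop]
    }
  }
  pos <- pos[pos >= 1 & pos <= len]
  unique(pos)
}

#' Simulate labelled molecules over the locus region
#'
#' Each molecule draws an allele (fair coin), a somatic tract length from
#' that allele's mosaicism model, a log-normal length and a uniform start.
#' Reference labels within the footprint are copied; the reference repeat
#' tract is replaced by `3 * tract` bp, shifting downstream labels. Strand
#' is random and label offsets are reported in molecule frame. Noise (label
#' dropout, spurious labels, Gaussian interval sizing error, sub-resolution
#' collapse) is then applied per [noise_model()].
#'
#' @param profile An `ogm_tissue_profile`.
#' @param region An `ogm_region` from [simulate_region()].
#' @param n_molecules Number of molecules to emit.
#' @param lengths See [length_model()].
#' @param noise See [noise_model()].
#' @param seed RNG seed.
#' @param span_only If `TRUE`, molecule starts are restricted so every
#'   molecule's footprint covers the locus flanks (used for calibration
#'   experiments; lengths shorter than the locus span are redrawn).
#' @param start_id First molecule id.
#' @return An `ogm_simulation`: list with `molecules` (list of
#'   `ogm_molecule`) and `truth` (data frame: `molecule_id`, `allele`,
#'   `truth_repeats`, `covers_locus`, `spanning`, `start`, `strand`,
#'   `length`). `covers_locus` marks footprints containing both locus flank
#'   markers; `spanning` additionally requires >= 3 reference labels on each
#'   flank within the footprint (the aligner's minimum flank support),
#'   i.e. the molecules the pipeline can recover; both are assessed before
#'   noise.
#' @export
simulate_molecules <- function(profile, region, n_molecules,
                               lengths = length_model(),
                               noise = noise_model(), seed = 1,
                               span_only = FALSE, start_id = 1L) {
  stopifnot(inherits(profile, "ogm_tissue_profile"),
            inherits(region, "ogm_region"), n_molecules > 0)
  set.seed(seed)
  map <- region$map
  ref_pos <- map$labels$position
  rl <- map$contig_length
  up_pos <- region$locus$upstream[["position"]]
  dn_pos <- region$locus$downstream[["position"]]
  cp_pos <- if (is.null(region$locus$companion)) dn_pos
    else region$locus$companion[["position"]]
  mols <- vector("list", n_molecules)
  allele <- character(n_molecules)
  truth_rep <- integer(n_molecules)
  covers <- logical(n_molecules)
  span <- logical(n_molecules)
  starts <- numeric(n_molecules)
  strand <- character(n_molecules)
  lens <- numeric(n_molecules)
  for (m in seq_len(n_molecules)) {
    a <- if (stats::runif(1) < 0.5) "a" else "b"
    t_rep <- sample_tract(if (a == "a") profile$allele_a else profile$allele_b, 1)
    delta <- 3 * t_rep - region$ref_tract_len
    apos <- ref_pos
    shift <- apos > region$tract_end
    apos[shift] <- apos[shift] + delta
    alen <- rl + delta
    cp_a <- cp_pos + delta
    L <- round(stats::rlnorm(1, lengths$meanlog, lengths$sdlog))
    if (span_only) {
      span_need <- cp_a - up_pos + 1
      while (L <= span_need + 2)
        L <- round(stats::rlnorm(1, lengths$meanlog, lengths$sdlog))
      lo <- max(1, cp_a - L + 1)
      hi <- min(up_pos, alen - L + 1)
      s <- floor(stats::runif(1, lo, hi + 1))
    } else {
      L <- min(L, alen)
      s <- floor(stats::runif(1, 1, alen - L + 2))
    }
    inside <- apos >= s & apos <= s + L - 1
    offs <- apos[inside] - s + 1
    covers[m] <- s <= up_pos && (s + L - 1) >= cp_a
    # flank support counted from the flanking markers inclusive, mirroring
    # the aligner's minimum-support rule around the size-cost-free interval
    span[m] <- covers[m] &&
      sum(apos >= s & apos <= up_pos) >= 3 &&
      sum(apos >= dn_pos + delta & apos <= s + L - 1) >= 3
    st <- if (stats::runif(1) < 0.5) "+" else "-"
    if (st == "-") offs <- sort(L - offs + 1)
    offs <- apply_noise(offs, L, noise)
    id <- start_id + m - 1L
    mols[[m]] <- molecule(id, L, round(offs, 1),
                          origin = list(contig = map$contig_name, start = s,
                                        strand = st),
                          truth_repeats = t_rep)
    allele[m] <- a; truth_rep[m] <- t_rep
    starts[m] <- s; strand[m] <- st; lens[m] <- L
  }
  structure(list(
    molecules = mols,
    truth = data.frame(molecule_id = start_id + seq_len(n_molecules) - 1L,
                       allele = allele, truth_repeats = truth_rep,
                       covers_locus = covers, spanning = span,
                       start = starts, strand = strand, length = lens),
    region = region, profile = profile$name),
    class = "ogm_simulation")
}

#' Write a simulation truth table to TSV
#'
#' @param sim An `ogm_simulation`.
#' @param path Output TSV.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Molecule QC metrics
#'
#' `molecule_n50()`: length-weighted median molecule length.
#' `label_density()`: labels per 100 kb pooled over molecules.
#'
#' @param molecules List of `ogm_molecule`.
#' @return A single number.
#' @export
molecule_n50 <- function(molecules) {
  len <- sort(vapply(molecules, function(m) m$length, numeric(1)),
              decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1]]
}

#' @rdname molecule_n50
#' @export
label_density <- function(molecules) {
  nl <- sum(vapply(molecules, function(m) length(m$positions), numeric(1)))
  nl / sum(vapply(molecules, function(m) m$length, numeric(1))) * 1e5
}
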