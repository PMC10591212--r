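# Synthetic study generator: collagen-like multi-species sequence sets with
# planted, recorded substitutions, and simulated MALDI spectra with
# controllable degradation.  Everything is deterministic under a fixed
# seed, and every generated artefact is accompanied by its ground truth, so
# each pipeline stage can be scored without external data.

#' Configuration of a synthetic species set
#'
#' Collagen-likeness is enforced by construction: glycine at every third
#' position, proline-rich X/Y positions, K/R at a frequency that yields
#' tryptic fragments of realistic length.  Substitutions are planted only
#' at X/Y positions that are not G/K/R and not immediately after a K/R, and
#' replacements never introduce P/K/R, so tryptic boundaries stay identical
#' across species and positional homology pairing is exact.
#'
#' @param n_species Number of species (>= 2, default 4).
#' @param triplets_per_chain Gly-X-Y repeats per chain (default 340, a
#'   full-length fibrillar collagen chain of ~1020 residues).
#' @param substitution_rate Per X/Y-position substitution probability
#'   between the ancestral sequence and each species (default 0.008).
#' @param cleavage_density Probability that an X/Y draw is K or R (default
#'   0.06: mean tryptic fragment ~25 residues).
#' @param prop_pro Probability that an X/Y draw is proline (default 0.30).
#' @param propeptide_length N-propeptide residues preceding the mature
#'   chain (default 48; removed by the mature bounds).
#' @param seed Integer seed fixing all outputs (default 42).
#' @return List of class `synthetic_species_config`.
#' @export
synthetic_species_config <- function(n_species = 4L,
                                     triplets_per_chain = 340L,
                                     substitution_rate = 0.008,
                                     cleavage_density = 0.06,
                                     prop_pro = 0.30,
                                     propeptide_length = 48L,
                                     seed = 42L) {
  if (n_species < 2L) stop("n_species must be >= 2")
  rates <- c(substitution_rate, cleavage_density, prop_pro)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_species = as.integer(n_species),
                 triplets_per_chain = as.integer(triplets_per_chain),
                 substitution_rate = substitution_rate,
                 cleavage_density = cleavage_density,
                 prop_pro = prop_pro,
                 propeptide_length = as.integer(propeptide_length),
                 seed = as.integer(seed)),
            class = "synthetic_species_config")
}

.XY_OTHERS <- c("A", "S", "T", "V", "L", "D", "E", "N", "Q", "F", "H", "M")
.SUB_TARGETS <- c("A", "S", "T", "V", "L", "D", "E", "N", "Q", "F", "H")

.draw_xy <- function(n, cfg) {
  pool <- c("P", "K", "R", .XY_OTHERS)
  pr <- c(cfg$prop_pro, cfg$cleavage_density / 2, cfg$cleavage_density / 2,
          rep((1 - cfg$prop_pro - cfg$cleavage_density) /
                length(.XY_OTHERS), length(.XY_OTHERS)))
  sample(pool, n, replace = TRUE, prob = pr)
}

#' Generate a synthetic multi-species collagen profile set
#'
#' Builds one ancestral sequence per chain, then derives each species by
#' planting substitutions at eligible X/Y positions with the configured
#' rate.  Every substitution is recorded in the returned manifest
#' (species, chain, mature position, from, to).
#'
#' @param cfg A [synthetic_species_config()].
#' @return List with `profiles` (named list of [species_profile()]),
#'   `manifest` (`data.frame`) and `config`.
#' @export
make_species <- function(cfg = synthetic_species_config()) {
  stopifnot(inherits(cfg, "synthetic_species_config"))
  set.seed(cfg$seed)
  n_mat <- 3L * cfg$triplets_per_chain
  base <- lapply(.CHAIN_IDS, function(cid) {
    chars <- character(n_mat)
    g <- seq(1L, n_mat, by = 3L)
    chars[g] <- "G"
    xy <- setdiff(seq_len(n_mat), g)
    chars[xy] <- .draw_xy(length(xy), cfg)
    prop <- sample(c("G", .XY_OTHERS), cfg$propeptide_length, replace = TRUE)
    list(mature = chars, prop = prop)
  })
  names(base) <- .CHAIN_IDS
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  manifest <- list(); mk <- 0L
  profiles <- list()
  for (sp in species) {
    chains <- lapply(.CHAIN_IDS, function(cid) {
      chars <- base[[cid]]$mature
      g <- seq(1L, n_mat, by = 3L)
      eligible <- setdiff(seq_len(n_mat), g)
      eligible <- eligible[!chars[eligible] %in% c("K", "R", "G")]
      prev_kr <- eligible[eligible > 1L &
                            chars[eligible - 1L] %in% c("K", "R")]
      eligible <- setdiff(eligible, prev_kr)
      hit <- eligible[stats::runif(length(eligible)) < cfg$substitution_rate]
      for (pos in hit) {
        to <- sample(setdiff(.SUB_TARGETS, chars[pos]), 1L)
        mk <<- mk + 1L
        manifest[[mk]] <<- data.frame(species = sp, chain = cid,
                                      position = pos, from = chars[pos],
                                      to = to, stringsAsFactors = FALSE)
        chars[pos] <- to
      }
      residues <- paste(c(base[[cid]]$prop, chars), collapse = "")
      collagen_chain(sp, cid, residues,
                     mature_start = cfg$propeptide_length + 1L,
                     mature_end = cfg$propeptide_length + n_mat)
    })
    profiles[[sp]] <- species_profile(chains)
  }
  manifest <- if (mk) do.call(rbind, manifest) else
    data.frame(species = character(), chain = character(),
               position = integer(), from = character(), to = character(),
               stringsAsFactors = FALSE)
  list(profiles = profiles, manifest = manifest, config = cfg)
}

#' MALDI spectrum noise model
#'
#' @param shift_ppm Global calibration shift (ppm, default 20).
#' @param jitter_sd Per-peak mass jitter SD (Da, default 0.02).
#' @param fwhm Peak full width at half maximum (Da, default 0.35,
#'   reflector-mode scale).
#' @param intensity_meanlog,intensity_sdlog Log-normal peptide peak
#'   intensity parameters (defaults 4 and 0.5).
#' @param baseline_amp,baseline_decay Exponential chemical baseline
#'   amplitude and decay constant in Da (defaults 5 and 600).
#' @param noise_peak_rate Spurious peaks per 100 Da (default 0.5).
#' @param noise_sd Additive detector noise SD (default 0.4; the simulated
#'   noise floor sits at twice this value so it stays positive).
#' @param p_hydroxylation Hydroxylation probability per proline when an
#'   emission draws its modification state (default 0.2).
#' @param dropout Per-peptide dropout probability, emulating degradation
#'   and poor preservation (default 0.1).
#' @return List of class `spectrum_noise_model`.
#' @export
spectrum_noise_model <- function(shift_ppm = 20, jitter_sd = 0.02,
                                 fwhm = 0.35, intensity_meanlog = 4,
                                 intensity_sdlog = 0.5, baseline_amp = 5,
                                 baseline_decay = 600,
                                 noise_peak_rate = 0.5, noise_sd = 0.4,
                                 p_hydroxylation = 0.2, dropout = 0.1) {
  vals <- c(abs(shift_ppm), jitter_sd, fwhm, intensity_sdlog, baseline_amp,
            baseline_decay, noise_peak_rate, noise_sd, p_hydroxylation)
  if (any(vals < 0)) stop("noise model parameters must be nonnegative")
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  if (fwhm <= 0) stop("fwhm must be positive")
  structure(list(shift_ppm = shift_ppm, jitter_sd = jitter_sd, fwhm = fwhm,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 baseline_amp = baseline_amp,
                 baseline_decay = baseline_decay,
                 noise_peak_rate = noise_peak_rate, noise_sd = noise_sd,
                 p_hydroxylation = p_hydroxylation, dropout = dropout),
            class = "spectrum_noise_model")
}

#' @rdname spectrum_noise_model
#' @details `clean_noise_model()` is the noise-free limit: no calibration
#'   shift, no jitter, no spurious peaks, no baseline, no detector noise
#'   and (by default) no dropout; only the hydroxylation-state mixture
#'   remains.
#' @export
clean_noise_model <- function(dropout = 0) {
  spectrum_noise_model(shift_ppm = 0, jitter_sd = 0, noise_peak_rate = 0,
                       baseline_amp = 0, noise_sd = 0, dropout = dropout)
}

# digest a profile into a peptide table with base masses and proline counts
.peptide_table <- function(profile, dparams) {
  tab <- do.call(rbind, lapply(profile$chains, tryptic_peptides,
                               params = dparams))
  tab <- tab[!grepl("X", tab$sequence, fixed = TRUE), , drop = FALSE]
  tab$base_mz <- peptide_mh(tab$sequence)
  tab$n_pro <- vapply(strsplit(tab$sequence, "", fixed = TRUE),
                      function(ch) sum(ch == "P"), integer(1))
  rownames(tab) <- NULL
  tab
}

.simulate_one <- function(ptab, noise, sample_id, grid_step, mz_range) {
  n <- nrow(ptab)
  n_oh <- stats::rbinom(n, ptab$n_pro, noise$p_hydroxylation)
  dropped <- stats::runif(n) < noise$dropout
  mz_true <- ptab$base_mz + n_oh * mass_constants[["hydroxylation"]]
  mz_emit <- mz_true * (1 + noise$shift_ppm * 1e-6) +
    stats::rnorm(n, 0, noise$jitter_sd)
  height <- stats::rlnorm(n, noise$intensity_meanlog, noise$intensity_sdlog)
  truth <- data.frame(chain = ptab$chain, start = ptab$start,
                      sequence = ptab$sequence,
                      missed_cleavages = ptab$missed_cleavages,
                      n_oh = n_oh, mz_theoretical = mz_true,
                      mz_emitted = mz_emit, intensity = height,
                      dropped = dropped, stringsAsFactors = FALSE)
  keep <- !dropped & mz_emit > mz_range[1L] & mz_emit < mz_range[2L]
  span <- diff(mz_range)
  n_noise <- stats::rpois(1L, noise$noise_peak_rate * span / 100)
  noise_mz <- stats::runif(n_noise, mz_range[1L], mz_range[2L])
  noise_int <- stats::rlnorm(n_noise, noise$intensity_meanlog - 1,
                             noise$intensity_sdlog)
  x <- seq(mz_range[1L], mz_range[2L], by = grid_step)
  y <- noise$baseline_amp * exp(-(x - mz_range[1L]) / noise$baseline_decay) +
    pmax(stats::rnorm(length(x), 2 * noise$noise_sd, noise$noise_sd), 0)
  sigma <- noise$fwhm / 2.354820045
  add_peak <- function(mu, h) {
    lo <- max(1L, ceiling((mu - 5 * sigma - mz_range[1L]) / grid_step) + 1L)
    hi <- min(length(x), floor((mu + 5 * sigma - mz_range[1L]) / grid_step) + 1L)
    if (lo > hi) return()
    idx <- lo:hi
    y[idx] <<- y[idx] + h * exp(-0.5 * ((x[idx] - mu) / sigma)^2)
  }
  for (i in which(keep)) add_peak(mz_emit[i], height[i])
  for (i in seq_len(n_noise)) add_peak(noise_mz[i], noise_int[i])
  list(spectrum = maldi_spectrum(x, pmax(y, 0), sample_id = sample_id,
                                 centroided = FALSE),
       truth = truth,
       noise_peaks = data.frame(mz = noise_mz, intensity = noise_int))
}

#' Simulate one MALDI spectrum from a species profile
#'
#' Digests the profile, draws one hydroxylation state per peptide
#' (binomial over its prolines), applies dropout, calibration shift and
#' per-peak jitter, and renders Gaussian peak profiles over an exponential
#' baseline with additive detector noise and Poisson-distributed spurious
#' peaks.  Every emission (and every dropped peptide) is recorded in the
#' returned truth table.
#'
#' @param profile A [species_profile()].
#' @param noise A [spectrum_noise_model()].
#' @param dparams [digest_params()] used for the in-silico digest.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param grid_step m/z grid spacing in Da (default 0.1, ~3.5 points per
#'   default FWHM).
#' @param mz_range m/z window; default covers the digest's masses.
#' @param sample_id Sample label.
#' @return List with `spectrum`, `truth` and `noise_peaks`.
#' @export
simulate_spectrum <- function(profile, noise = spectrum_noise_model(),
                              dparams = digest_params(max_missed_cleavages = 1L),
                              seed = NULL, grid_step = 0.1,
                              mz_range = NULL, sample_id = "sim") {
  stopifnot(inherits(profile, "species_profile"),
            inherits(noise, "spectrum_noise_model"))
  if (!is.null(seed)) set.seed(seed)
  ptab <- .peptide_table(profile, dparams)
  if (is.null(mz_range))
    mz_range <- c(floor(min(ptab$base_mz)) - 50,
                  ceiling(max(ptab$base_mz) + 4 * 16) + 50)
  .simulate_one(ptab, noise, sample_id, grid_step, mz_range)
}

#' Simulate a labelled cohort of MALDI spectra
#'
#' Either a fixed number of spectra per species, or `n` spectra with
#' species drawn from `weights` (the dominant-species cohort analogue).
#' The truth manifest carries the true species per sample and suffices to
#' score identification accuracy, indeterminate rate and composition
#' recovery.
#'
#' @param profiles Named list of [species_profile()] objects.
#' @param n_per_species Spectra per species (ignored when `weights` given).
#' @param n Total spectra when sampling by `weights`.
#' @param weights Species sampling proportions (must sum to 1).
#' @param noise A [spectrum_noise_model()].
#' @param dparams [digest_params()].
#' @param seed Integer seed (default 42).
#' @param grid_step m/z grid spacing (default 0.1).
#' @return List with `spectra` (named list), `truth`
#'   (`data.frame(sample_id, species)`) and `emissions` (per-sample truth
#'   tables).
#' @export
simulate_cohort <- function(profiles, n_per_species = NULL, n = NULL,
                            weights = NULL,
                            noise = spectrum_noise_model(),
                            dparams = digest_params(max_missed_cleavages = 1L),
                            seed = 42L, grid_step = 0.1) {
  set.seed(seed)
  sp <- names(profiles)
  if (!is.null(weights)) {
    if (length(weights) != length(sp)) stop("one weight per species")
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
    if (is.null(n)) stop("give n when sampling by weights")
    draw <- sample(sp, n, replace = TRUE, prob = weights)
  } else {
    if (is.null(n_per_species)) stop("give n_per_species or weights + n")
    draw <- rep(sp, each = n_per_species)
  }
  empty_truth <- data.frame(sample_id = character(), species = character(),
                            stringsAsFactors = FALSE)
  if (length(draw) == 0L)
    return(list(spectra = list(), truth = empty_truth, emissions = list()))
  ptabs <- lapply(profiles, .peptide_table, dparams = dparams)
  all_mz <- unlist(lapply(ptabs, `[[`, "base_mz"), use.names = FALSE)
  mz_range <- c(floor(min(all_mz)) - 50, ceiling(max(all_mz) + 64) + 50)
  spectra <- vector("list", length(draw))
  emissions <- vector("list", length(draw))
  ids <- sprintf("sample_%04d", seq_along(draw))
  for (i in seq_along(draw)) {
    sim <- .simulate_one(ptabs[[draw[i]]], noise, ids[i], grid_step,
                         mz_range)
    spectra[[i]] <- sim$spectrum
    emissions[[i]] <- sim$truth
  }
  names(spectra) <- names(emissions) <- ids
  list(spectra = spectra,
       truth = data.frame(sample_id = ids, species = draw,
                          stringsAsFactors = FALSE),
       emissions = emissions)
}
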