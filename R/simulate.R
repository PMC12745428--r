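#' Band-specific coupling specification for the EEG simulator
#'
#' Describes the ground-truth interactions the simulator plants in one
#' frequency band: a set of directed channel pairs, each carrying a phase
#' lag (radians) and a coupling strength, plus the standard deviation of
#' the additive white noise and the strength of the zero-lag
#' volume-conduction-like mixing.
#'
#' @param band band name (one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`).
#' @param pairs data.frame with columns `from`, `to` (montage labels),
#'   `lag` (radians, in `(-pi, pi]`) and `strength` (in `[0, 1]`); an
#'   optional `freq` column assigns each pair its own carrier frequency
#'   (Hz) inside the band (default: band midpoint for every pair).
#' @param freq_hz default carrier frequency for pairs without a `freq`
#'   entry; defaults to the band midpoint.
#' @param noise_sd standard deviation of the independent Gaussian noise
#'   added to every channel, expressed per sample at a 250 Hz reference
#'   rate (same units as the unit-amplitude oscillators); the simulator
#'   scales it by `sqrt(fs/250)` so the noise spectral density - and
#'   hence every per-frequency-bin signal-to-noise ratio - does not
#'   depend on the simulation rate.
#' @param mixing_strength scalar `>= 0` scaling the symmetric
#'   nearest-neighbor zero-lag mixing across scalp channels.
#' @param phase_diffusion rate (rad per sqrt-second) of the Brownian
#'   phase drift shared by the source and target of each pair. Drift
#'   decorrelates successive analysis windows, as the finite coherence
#'   time of real band-limited EEG rhythms does, without disturbing the
#'   pair's constant phase lag. 0 gives strictly periodic oscillators.
#' @return A list of class `CouplingSpec`.
#' @seealso [generateRecording()], [generateCohort()]
#' @export
couplingSpec <- function(band, pairs, freq_hz = NULL, noise_sd = 1,
                         mixing_strength = 0, phase_diffusion = 2) {
  band <- match.arg(band, names(standardBands()))
  b <- standardBands()[[band]]
  if (is.null(freq_hz)) freq_hz <- (b[1] + b[2]) / 2
  pairs <- as.data.frame(pairs)
  if (nrow(pairs)) {
    stopifnot(all(c("from", "to", "lag", "strength") %in% names(pairs)))
    if (is.null(pairs$freq)) pairs$freq <- freq_hz
    if (any(pairs$lag <= -pi | pairs$lag > pi))
      stop("coupling lags must lie in (-pi, pi]")
    if (any(pairs$strength < 0 | pairs$strength > 1))
      stop("coupling strengths must lie in [0, 1]")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (mixing_strength < 0) stop("mixing_strength must be >= 0")
  if (phase_diffusion < 0) stop("phase_diffusion must be >= 0")
  structure(list(band = band, pairs = pairs, freq_hz = freq_hz,
                 noise_sd = noise_sd, mixing_strength = mixing_strength,
                 phase_diffusion = phase_diffusion),
            class = "CouplingSpec")
}

#' Default ground-truth coupling of the simulated cohort
#'
#' The cohort's reference ("control") interaction structure in the alpha
#' and beta bands, three graded tiers per band:
#' \itemize{
#'   \item two hemispheric ring lattices (strength 1.0): independent
#'     oscillators couple scalp-neighboring electrodes around each
#'     hemisphere. Triangle-free and confined to one hemisphere, this is
#'     the residual local synchrony that survives attenuation;
#'   \item a triangle-closing chord tier (strength 0.45): ring
#'     second-neighbor couplings whose triangles carry the network's
#'     clustering and local efficiency;
#'   \item a hub-star process (strength 0.5): one shared oscillator on
#'     the vertex electrode Cz drives all 18 other nodes at phase
#'     offsets staggered over 30-150 degrees - the interhemispheric
#'     integration backbone that keeps every node within two hops.
#' }
#' Uniformly attenuating the strengths (the patient model) sinks the two
#' weak tiers under the wPLI noise floor while the rings survive:
#' patient networks degrade toward triangle-poor, noise-ranked
#' topologies with weakened interhemispheric integration - lower
#' clustering, local efficiency and global efficiency than controls,
#' the qualitative pattern reported for motor-task EEG in upper-limb
#' spasticity - while controls retain the designed small-world-like
#' organization. Ring/chord oscillators cycle carriers over the lower
#' band interior; the star keeps a cleaner slot near the upper band
#' edge. Delta and theta carry no planted coupling (noise-level
#' connectivity).
#'
#' @param bands bands to populate (default alpha and beta).
#' @param strength amplitude of the star-process members (default 0.5).
#' @param noise_sd,mixing_strength,phase_diffusion passed to
#'   [couplingSpec()] (defaults 2, 0.2, 2).
#' @return Named list of `CouplingSpec`, one per band in
#'   `names(standardBands())`.
#' @export
defaultCoupling <- function(bands = c("alpha", "beta"), strength = 0.5,
                            noise_sd = 2, mixing_strength = 0.2,
                            phase_diffusion = 2) {
  m <- standardMontage()
  hub <- "Cz"
  ## two hemispheric rings walking each scalp half between neighbors;
  ## Fz joins the left loop and Pz the right so all 18 non-hub nodes are
  ## covered
  ringL <- c("Fp1", "F3", "Fz", "C3", "P3", "O1", "T5", "T3", "F7")
  ringR <- c("Fp2", "F4", "Pz", "C4", "P4", "O2", "T6", "T4", "F8")
  stopifnot(setequal(c(ringL, ringR), setdiff(m$labels, hub)))
  rim <- c(ringL, ringR)
  nr <- length(rim)
  ## star: one shared oscillator process; the hub drives all 18 nodes at
  ## offsets spread over (30, 150) degrees, so every spoke - and every
  ## phase-distant node pair - keeps a strong lagged (imaginary)
  ## cross-spectral component: the interhemispheric integration backbone
  star <- data.frame(from = hub, to = rim,
                     lag = pi / 6 + (seq_len(nr) - 1L) / (nr - 1L) * 2 * pi / 3,
                     strength = strength, source = "star")
  ## local lattices: independent unit-amplitude oscillators per edge,
  ## ring distance 1 strong (the residual local synchrony patients keep,
  ## triangle-free and confined to one hemisphere) and distance 2 weak
  ## (the triangle-closing tier only intact coupling retains)
  chordh <- function(nodes, dist, s, tag) {
    n <- length(nodes)
    data.frame(from = nodes, to = nodes[(seq_len(n) - 1L + dist) %% n + 1L],
               lag = pi / 2, strength = s,
               source = paste0(tag, nodes))
  }
  pairs <- rbind(star,
                 chordh(ringL, 1L, 1.0, "rL"), chordh(ringR, 1L, 1.0, "rR"),
                 chordh(ringL, 2L, 0.45, "cL"), chordh(ringR, 2L, 0.45, "cR"))
  out <- lapply(names(standardBands()), function(b) {
    p <- if (b %in% bands) pairs else pairs[0, ]
    if (nrow(p)) {
      ## lattice carriers cycle the lower band interior; the star keeps
      ## a clean slot near the upper band edge
      bd <- standardBands()[[b]]
      w <- bd[2] - bd[1]
      nl <- max(2L, floor(0.6 * w))
      slot <- (seq_len(nrow(p)) * 5L) %% nl
      p$freq <- bd[1] + 0.5 + slot * (0.55 * w) / nl
      p$freq[p$source == "star"] <- bd[2] - 0.25 * w
    }
    couplingSpec(b, p, noise_sd = noise_sd,
                 mixing_strength = mixing_strength,
                 phase_diffusion = phase_diffusion)
  })
  names(out) <- names(standardBands())
  out
}

#' Simulate one multi-channel EEG recording with known coupling
#'
#' Generates a continuous 21-channel recording (19 montage nodes + A1/A2
#' references) as a sum of band-specific coupled oscillators, independent
#' Gaussian noise, and optional zero-lag nearest-neighbor mixing. Each
#' trial of each task occupies one segment; the source oscillator of every
#' coupled pair draws a fresh uniform phase per trial while the pair's
#' phase lag is held constant across trials - exactly the kind of
#' consistent lagged synchrony the weighted phase lag index detects,
#' while the zero-lag mixing it must ignore is instantaneous.
#'
#' @param montage a montage from [standardMontage()].
#' @param coupling named list of [couplingSpec()] objects, one per band.
#' @param n_trials trials per task (`>= 1`).
#' @param fs sampling rate in Hz; must exceed twice the highest coupled
#'   carrier frequency.
#' @param pre_s,post_s seconds of signal before/after each cue retained in
#'   the epoch window (defaults 1 and 4).
#' @param gap_s guard interval between consecutive trials (s).
#' @param tasks character vector of task labels to simulate.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   recording bit for bit.
#' @return An [EEGRecording-class] with one cue event per trial per task.
#' @examples
#' cpl <- list(alpha = couplingSpec("alpha",
#'   data.frame(from = "C3", to = "F3", lag = pi / 2, strength = 1),
#'   noise_sd = 0.05))
#' rec <- generateRecording(coupling = cpl, n_trials = 4, fs = 250,
#'                          tasks = "fist", seed = 1)
#' rec
#' @export
generateRecording <- function(montage = standardMontage(), coupling,
                              n_trials = 20, fs = 1000, pre_s = 1,
                              post_s = 4, gap_s = 1,
                              tasks = c("fist", "elbow", "wrist"),
                              seed = 1) {
  stopifnot(n_trials >= 1)
  all_labels <- c(montage$labels, montage$refs)
  fmax <- 0
  for (cs in coupling) {
    if (!inherits(cs, "CouplingSpec")) stop("coupling entries must be CouplingSpec")
    if (nrow(cs$pairs)) {
      bad <- setdiff(unique(c(cs$pairs$from, cs$pairs$to)), all_labels)
      if (length(bad))
        stop("unknown channel label in coupling: ", paste(bad, collapse = ", "))
      fmax <- max(fmax, cs$pairs$freq)
    }
  }
  if (fmax > 0 && fs < 2 * fmax)
    stop(sprintf("fs = %g Hz is below twice the highest coupled frequency (%g Hz)", fs, fmax))

  seg_n <- round((pre_s + post_s + gap_s) * fs)
  cue_off <- round(pre_s * fs) + 1L           # cue sample within a segment
  n_seg <- n_trials * length(tasks)
  n_samp <- seg_n * n_seg
  n_ch <- length(all_labels)
  mixW <- montageNeighbors(montage)
  mixW <- mixW / pmax(rowSums(mixW), 1)       # row-normalized smoothing

  withSeed(seed, {
    ## oscillator (neural) field, mixed by volume conduction below;
    ## sensor noise is per-electrode and added unmixed afterwards
    x <- matrix(0, n_ch, n_samp)
    rownames(x) <- all_labels
    tloc <- (seq_len(seg_n) - 1) / fs           # segment-local time axis
    for (cs in coupling) {
      if (!nrow(cs$pairs)) next
      sd_step <- cs$phase_diffusion / sqrt(fs)  # Brownian phase increment
      pr <- cs$pairs
      if (is.null(pr$source)) pr$source <- paste0("p", seq_len(nrow(pr)))
      ## Resolve each source group into one oscillator process carrying a
      ## set of channels at fixed phase offsets: the first 'from' of a
      ## group is its driver (offset 0, unit amplitude); every 'to'
      ## enters at the accumulated offset with amplitude = strength.
      ## A channel contributes once per group (first assignment wins), so
      ## chains and stars share one trajectory without amplitude pileup.
      for (src in unique(pr$source)) {
        rows <- pr[pr$source == src, , drop = FALSE]
        off <- c(); amp <- c()
        for (p in seq_len(nrow(rows))) {
          f <- rows$from[p]; t <- rows$to[p]
          if (!f %in% names(off)) {
            off[f] <- 0; amp[f] <- 1
          }
          if (!t %in% names(off)) {
            off[t] <- off[[f]] + rows$lag[p]
            amp[t] <- rows$strength[p]
          }
        }
        w <- 2 * pi * rows$freq[1L]
        phase0 <- runif(n_seg, -pi, pi)
        for (g in seq_len(n_seg)) {
          idx <- (g - 1L) * seg_n + seq_len(seg_n)
          ## shared trajectory: fresh uniform phase each trial plus
          ## Brownian drift; members repeat it at constant offsets
          drift <- if (sd_step > 0) cumsum(rnorm(seg_n, 0, sd_step)) else 0
          phi <- w * tloc + phase0[g] + drift
          for (ch in names(off))
            x[ch, idx] <- x[ch, idx] + amp[[ch]] * sin(phi - off[[ch]])
        }
      }
    }
    ## zero-lag volume-conduction-like mixing of the oscillator field
    ## over the scalp nodes
    mix <- max(vapply(coupling, function(cs) cs$mixing_strength, numeric(1)), 0)
    if (mix > 0) {
      nodes <- montage$labels
      x[nodes, ] <- x[nodes, ] + mix * (mixW %*% x[nodes, ])
    }
    ## independent per-electrode sensor noise: noise_sd is calibrated as
    ## the per-sample SD at a 250 Hz reference rate and scaled by
    ## sqrt(fs/250), keeping the noise spectral density - and therefore
    ## every per-bin signal-to-noise ratio - invariant to the simulation
    ## rate, so generating at a high rate and decimating is equivalent
    ## to generating at the analysis rate directly
    sds <- vapply(coupling, function(cs) cs$noise_sd, numeric(1))
    x <- x + matrix(rnorm(n_ch * n_samp), n_ch, n_samp) *
      max(sds) * sqrt(fs / 250)
    events <- data.frame(
      sample = cue_off + seg_n * (seq_len(n_seg) - 1L),
      task = rep(tasks, each = n_trials))
    EEGRecording(x, fs = fs, labels = all_labels, events = events)
  })
}

#' MAS grade coding
#'
#' Numeric coding of the Modified Ashworth Scale grades used for rank
#' correlations: `0 -> 0`, `1 -> 1`, `1+ -> 1.5`, `2 -> 2` (conventional
#' midpoint coding of the `1+` grade).
#'
#' @param grade character vector of grades in `c("0", "1", "1+", "2")`.
#' @return Numeric codes.
#' @export
masCode <- function(grade) {
  map <- c("0" = 0, "1" = 1, "1+" = 1.5, "2" = 2)
  bad <- setdiff(unique(grade), names(map))
  if (length(bad)) stop("unknown MAS grade: ", paste(bad, collapse = ", "))
  unname(map[grade])
}

## Default monotone attenuation -> MAS rule: rank patients by their true
## coupling factor (most attenuated first) and split ranks into the four
## grades 2, 1+, 1, 0. Guarantees severity rises with attenuation.
masLinkByRank <- function(factors) {
  grades <- c("2", "1+", "1", "0")
  n <- length(factors)
  q <- ceiling(rank(factors, ties.method = "first") / n * 4)
  grades[q]
}

#' Simulate a patient/control cohort with an attenuation-severity link
#'
#' Controls receive the base coupling unchanged. Each patient's coupling
#' strengths are multiplied by a subject-specific factor drawn around
#' `patient_attenuation` (factor `= 1 - (1 - a) * u`, `u ~ U(0.85, 1.15)`,
#' clipped to `[0, 1]`; at `a = 1` the factor is exactly 1 so the groups
#' are exchangeable - the moderate spread keeps all patients within the
#' moderate-severity range the cohort models while leaving four
#' distinguishable severity grades). MAS-like grades are assigned by a
#' monotone rule so
#' clinical severity co-varies with the true attenuation, and a
#' configurable fraction of patients is right-affected.
#'
#' @param n_per_group subjects per group (`>= 2`).
#' @param base_coupling named per-band list of [couplingSpec()]; default
#'   [defaultCoupling()].
#' @param patient_attenuation mean multiplicative factor in `[0, 1]`
#'   applied to patient coupling strengths (1 = no group difference).
#' @param mas_link function mapping the vector of patient factors to MAS
#'   grades; default ranks factors into grades 2, 1+, 1, 0.
#' @param right_fraction fraction of patients with right-sided
#'   involvement (default 1/8).
#' @param n_trials,fs,pre_s,post_s,gap_s,tasks forwarded to
#'   [generateRecording()].
#' @param seed master seed; per-subject seeds are derived from it.
#' @return List of `SimulatedSubject` lists with elements `subject_id`,
#'   `group`, `affected_side`, `mas_upper`, `mas_hand`, `attenuation`
#'   (the subject's true factor; 1 for controls), `ground_truth` (per-band
#'   coupling), `seed`, and `recording`.
#' @examples
#' coh <- generateCohort(2, n_trials = 2, fs = 200, post_s = 2,
#'                       tasks = "fist", seed = 3)
#' sapply(coh, `[[`, "group")
#' @export
generateCohort <- function(n_per_group = 8,
                           base_coupling = defaultCoupling(),
                           patient_attenuation = 0.3,
                           mas_link = masLinkByRank,
                           right_fraction = 1 / 8,
                           n_trials = 20, fs = 1000, pre_s = 1, post_s = 4,
                           gap_s = 1, tasks = c("fist", "elbow", "wrist"),
                           seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (patient_attenuation < 0 || patient_attenuation > 1)
    stop("patient_attenuation must lie in [0, 1]")
  seeds <- deriveSeeds(seed, 2L * n_per_group + 1L)
  factors <- withSeed(seeds[2L * n_per_group + 1L], {
    if (patient_attenuation == 1) rep(1, n_per_group)
    else pmin(1, pmax(0, 1 - (1 - patient_attenuation) *
                           runif(n_per_group, 0.85, 1.15)))
  })
  mas_u <- mas_link(factors)
  ## hand grade: same monotone rule on a slightly perturbed factor
  mas_h <- withSeed(seeds[2L * n_per_group + 1L],
                    mas_link(factors + rnorm(n_per_group, 0, 0.05)))
  n_right <- round(right_fraction * n_per_group)
  sides <- rep("left", n_per_group)
  if (n_right > 0) sides[seq_len(n_right)] <- "right"

  attenuate <- function(cpl, f) {
    lapply(cpl, function(cs) {
      if (nrow(cs$pairs)) cs$pairs$strength <- pmin(1, cs$pairs$strength * f)
      cs
    })
  }
  subjects <- vector("list", 2L * n_per_group)
  for (i in seq_len(n_per_group)) {
    gt <- attenuate(base_coupling, factors[i])
    subjects[[i]] <- list(
      subject_id = sprintf("pat%02d", i), group = "patient",
      affected_side = sides[i], mas_upper = mas_u[i], mas_hand = mas_h[i],
      attenuation = factors[i], ground_truth = gt, seed = seeds[i],
      recording = generateRecording(coupling = gt, n_trials = n_trials,
                                    fs = fs, pre_s = pre_s, post_s = post_s,
                                    gap_s = gap_s, tasks = tasks,
                                    seed = seeds[i]))
  }
  for (i in seq_len(n_per_group)) {
    subjects[[n_per_group + i]] <- list(
      subject_id = sprintf("ctl%02d", i), group = "control",
      affected_side = NA_character_, mas_upper = NA_character_,
      mas_hand = NA_character_, attenuation = 1,
      ground_truth = base_coupling, seed = seeds[n_per_group + i],
      recording = generateRecording(coupling = base_coupling,
                                    n_trials = n_trials, fs = fs,
                                    pre_s = pre_s, post_s = post_s,
                                    gap_s = gap_s, tasks = tasks,
                                    seed = seeds[n_per_group + i]))
  }
  subjects
}

#' Cohort manifest table
#'
#' @param cohort list of subjects from [generateCohort()].
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `affected_side`, `mas_upper`, `mas_hand`, `seed`.
#' @export
cohortManifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               affected_side = s$affected_side, mas_upper = s$mas_upper,
               mas_hand = s$mas_hand, seed = s$seed,
               stringsAsFactors = FALSE)))
}
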