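#' Design of synthetic calcium-imaging experiments
#'
#' Generative specification of single-cell calcium indicator traces: frames
#' at `frame_rate_hz` (default 0.8 s^-1), ligand stimulation at
#' `stim_time_s` (default 80 s), a post-stimulation fluorescence rise whose
#' fold size follows the Hill dose-response of the spectral design, and an
#' exponential decay back to baseline. Setting `calcium_present = FALSE`
#' forces a zero effect, emulating a calcium-free bath in which the ligand
#' response is abolished.
#'
#' @slot frame_rate_hz sampling rate (s^-1).
#' @slot stim_time_s stimulation onset (s), inside the record.
#' @slot duration_s trace duration (s).
#' @slot n_cells number of cells.
#' @slot baseline_f resting fluorescence (a.u.).
#' @slot peak_fold_at_emax maximal fold response at full effect.
#' @slot decay_tau_s exponential decay time constant (s).
#' @slot noise_cv frame noise as a fraction of baseline fluorescence.
#' @slot response_cv log-normal cell-to-cell response variability (sdlog).
#' @slot calcium_present logical; `FALSE` forces zero effect.
#' @slot seed integer seed.
#' @export
setClass("CalciumDesign",
         representation(frame_rate_hz = "numeric", stim_time_s = "numeric",
                        duration_s = "numeric", n_cells = "integer",
                        baseline_f = "numeric", peak_fold_at_emax = "numeric",
                        decay_tau_s = "numeric", noise_cv = "numeric",
                        response_cv = "numeric", calcium_present = "logical",
                        seed = "integer"))

setValidity("CalciumDesign", function(object) {
  if (object@frame_rate_hz <= 0) return("frame_rate_hz must be positive")
  if (object@stim_time_s <= 0 || object@stim_time_s >= object@duration_s)
    return("stim_time_s must lie inside the trace duration")
  if (object@n_cells < 1L) return("n_cells must be at least 1")
  if (object@baseline_f <= 0) return("baseline_f must be positive")
  if (object@peak_fold_at_emax < 1) return("peak_fold_at_emax must be at least 1")
  if (object@decay_tau_s <= 0) return("decay_tau_s must be positive")
  if (object@noise_cv < 0 || object@response_cv < 0)
    return("noise_cv and response_cv must be non-negative")
  TRUE
})

#' @param frame_rate_hz,stim_time_s,duration_s,n_cells,baseline_f see slots.
#' @param peak_fold_at_emax,decay_tau_s,noise_cv,response_cv see slots.
#' @param calcium_present,seed see slots.
#' @rdname CalciumDesign-class
#' @export
calciumDesign <- function(frame_rate_hz = 0.8, stim_time_s = 80,
                          duration_s = 300, n_cells = 20L, baseline_f = 100,
                          peak_fold_at_emax = 2.5, decay_tau_s = 60,
                          noise_cv = 0.02, response_cv = 0.25,
                          calcium_present = TRUE, seed = 1L) {
  new("CalciumDesign", frame_rate_hz = frame_rate_hz, stim_time_s = stim_time_s,
      duration_s = duration_s, n_cells = as.integer(n_cells),
      baseline_f = baseline_f, peak_fold_at_emax = peak_fold_at_emax,
      decay_tau_s = decay_tau_s, noise_cv = noise_cv, response_cv = response_cv,
      calcium_present = calcium_present, seed = as.integer(seed))
}

setMethod("show", "CalciumDesign", function(object) {
  cat(sprintf(paste0("CalciumDesign: %d cells, %.2g s^-1, stim %.0f s / %.0f s;",
                     " peak fold %.2g, calcium %s\n"),
              object@n_cells, object@frame_rate_hz, object@stim_time_s,
              object@duration_s, object@peak_fold_at_emax,
              if (object@calcium_present) "present" else "absent"))
})

#' Generate synthetic calcium traces for one dose
#'
#' Each cell's fluorescence sits at baseline before stimulation and, after
#' it, rises by a fold `1 + (peak_fold_at_emax - 1) * effect * v` with
#' log-normal per-cell variability `v`, decaying exponentially; the effect
#' fraction comes from the Hill model of `design` and is zero when
#' `calcium_present` is `FALSE`.
#'
#' @param cal a [CalciumDesign-class].
#' @param dose_um ligand dose in micromolar.
#' @param design a [SyntheticDesign-class] supplying the Hill parameters.
#' @param seed integer seed (defaults to the calcium design seed).
#' @return list of [CalciumTrace-class], one per cell.
#' @export
generateCalciumTraces <- function(cal, dose_um, design = syntheticDesign(),
                                  seed = cal@seed) {
  validObject(cal)
  if (dose_um < 0) stop("dose must be non-negative")
  effect <- if (cal@calcium_present) effectFraction(dose_um, design) else 0
  t <- seq(0, cal@duration_s, by = 1 / cal@frame_rate_hz)
  post <- t >= cal@stim_time_s
  decay <- ifelse(post, exp(-(t - cal@stim_time_s) / cal@decay_tau_s), 0)
  withSeed(seed, {
    lapply(seq_len(cal@n_cells), function(i) {
      v <- stats::rlnorm(1, 0, cal@response_cv)
      fold <- 1 + (cal@peak_fold_at_emax - 1) * effect * v
      f <- cal@baseline_f * (1 + (fold - 1) * decay) +
        stats::rnorm(length(t), sd = cal@noise_cv * cal@baseline_f)
      CalciumTrace(t, pmax(f, .Machine$double.eps), cal@stim_time_s,
                   metadata = list(cell = i, dose_um = dose_um,
                                   calcium_present = cal@calcium_present))
    })
  })
}
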