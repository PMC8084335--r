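#' Experiment schedule for a named condition
#'
#' Builds the phase structure common to all conditions: 50 baseline trials
#' and 5 pre-field null trials, then 155 adaptation trials in the condition's
#' force field, then 150 de-adaptation trials in the null field — except
#' LIPF_PEC, whose de-adaptation runs under the partial error clamp. Rest
#' breaks (after adaptation trials 50, 100 and 150) are annotations only and
#' have no simulated effect.
#'
#' @param condition One of `"VDCF"`, `"LIPF_NULL"`, `"PSPF"`, `"CPVF"`,
#'   `"LIPF_PEC"`.
#' @param gains Named list of field gains (`b1`, `k1`, `k2`) used to build
#'   the adaptation-phase [field_spec()]; defaults are the experimental
#'   gains. Model simulations pass their own.
#' @param pec [channel_spec()] used in LIPF_PEC de-adaptation.
#' @return An object of class `"schedule"`: a list of phases, each with
#'   `label`, `n_trials`, `field` and optional `channel`, plus the rest-break
#'   annotation.
#' @export
#' @examples
#' sch <- make_schedule("LIPF_NULL")
#' sum(vapply(sch$phases, `[[`, numeric(1), "n_trials"))  # 360 trials
make_schedule <- function(condition = c("VDCF", "LIPF_NULL", "PSPF", "CPVF",
                                        "LIPF_PEC"),
                          gains = list(b1 = 14, k1 = 60, k2 = 20868),
                          pec = channel_spec()) {
  condition <- match.arg(condition)
  fld <- function(kind) field_spec(kind, b1 = gains$b1, k1 = gains$k1,
                                   k2 = gains$k2)
  null_f <- field_spec("NULL")
  adapt_field <- switch(condition,
    VDCF = fld("VDCF"),
    LIPF_NULL = , LIPF_PEC = fld("LIPF"),
    PSPF = fld("PSPF"),
    CPVF = fld("CPVF"))
  deadapt_channel <- if (condition == "LIPF_PEC") pec else NULL
  structure(list(
    condition = condition,
    phases = list(
      list(label = "baseline",      n_trials = 50L,  field = null_f,
           channel = NULL),
      list(label = "pre_null",      n_trials = 5L,   field = null_f,
           channel = NULL),
      list(label = "adaptation",    n_trials = 155L, field = adapt_field,
           channel = NULL),
      list(label = "de_adaptation", n_trials = 150L, field = null_f,
           channel = deadapt_channel)
    ),
    rest_breaks_after_adapt_trials = c(50L, 100L, 150L)
  ), class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("<schedule> condition %s\n", x$condition))
  for (ph in x$phases)
    cat(sprintf("  %-14s %3d trials, field %s%s\n", ph$label, ph$n_trials,
                ph$field$kind,
                if (!is.null(ph$channel)) " + error-clamp channel" else ""))
  invisible(x)
}

#' Total trial count of a schedule
#' @param schedule A [make_schedule()] result.
#' @export
schedule_length <- function(schedule) {
  sum(vapply(schedule$phases, `[[`, integer(1L), "n_trials"))
}
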