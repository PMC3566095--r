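## Validation arithmetic for a labeled screening cascade: enrichment factor,
## sensitivity and specificity per stage and over the whole workflow.

#' Survivor counts for one screening stage
#'
#' Bookkeeping record for a filtering step applied to a labeled pool:
#' how many actives and decoys entered the stage and how many survived it.
#'
#' @param actives_in,decoys_in Number of actives / decoys entering the stage.
#' @param actives_out,decoys_out Number of actives / decoys surviving it.
#' @return An object of class `stage_counts`.
#' @examples
#' stage_counts(135, 2204, 111, 964)
#' @export
stage_counts <- function(actives_in, decoys_in, actives_out, decoys_out) {
  for (v in list(actives_in, decoys_in, actives_out, decoys_out)) {
    if (!is_count(v)) stopf("stage counts must be non-negative integers")
  }
  if (actives_out > actives_in) stopf("actives_out exceeds actives_in")
  if (decoys_out > decoys_in) stopf("decoys_out exceeds decoys_in")
  structure(
    list(actives_in = actives_in, decoys_in = decoys_in,
         actives_out = actives_out, decoys_out = decoys_out),
    class = "stage_counts"
  )
}

#' Enrichment factor, sensitivity and specificity of one stage
#'
#' The enrichment factor (EF) is the quotient between the fraction of actives
#' in the pool after the stage and the fraction of actives before it:
#' \deqn{EF = \frac{a_{out}/(a_{out}+d_{out})}{a_{in}/(a_{in}+d_{in})}}
#' Sensitivity is the percentage of actives retained,
#' \eqn{Se = 100\, a_{out}/a_{in}}; specificity is the percentage of decoys
#' rejected, \eqn{Sp = 100\,(d_{in}-d_{out})/d_{in}}.
#'
#' @param counts A [stage_counts()] object.
#' @return An object of class `stage_metrics` with fields `ef`, `se`, `sp`
#'   (full precision; use [format()] or [round_metrics()] for 2-dp display).
#' @examples
#' stage_metrics(stage_counts(135, 2204, 111, 964))  # EF 1.79
#' @export
stage_metrics <- function(counts) {
  stopifnot(inherits(counts, "stage_counts"))
  a_in <- counts$actives_in; d_in <- counts$decoys_in
  a_out <- counts$actives_out; d_out <- counts$decoys_out
  if (a_in == 0) stopf("EF/Se undefined: no actives entered the stage")
  if (d_in == 0) stopf("Sp undefined: no decoys entered the stage")
  if (a_out + d_out == 0) stopf("EF undefined: empty survivor set")
  ef <- (a_out / (a_out + d_out)) / (a_in / (a_in + d_in))
  se <- 100 * a_out / a_in
  sp <- 100 * (d_in - d_out) / d_in
  structure(list(ef = ef, se = se, sp = sp), class = "stage_metrics")
}

#' Overall cascade metrics from an ordered chain of stage counts
#'
#' Treats the first stage's input pool as the initial library and the last
#' stage's survivors as the final hit set, and computes overall EF, Se and Sp
#' together with the maximum achievable enrichment
#' `ef_max = (a_init + d_init) / a_init` (attained when only actives survive)
#' and `ef_pct = 100 * EF / ef_max`.
#'
#' @param stages A list of [stage_counts()] in cascade order. Consecutive
#'   stages must chain: each stage's inputs equal the previous survivors.
#' @return A `stage_metrics` object with extra fields `ef_max` and `ef_pct`.
#' @examples
#' chain <- list(
#'   stage_counts(135, 2204, 111, 964),
#'   stage_counts(111, 964, 72, 382),
#'   stage_counts(72, 382, 65, 102)
#' )
#' overall_metrics(chain)  # EF 6.15 for the 211/3122 pool is obtained by
#' # prepending the antipharmacophore counts stage_counts(211, 3122, 135, 2204)
#' @export
overall_metrics <- function(stages) {
  if (!is.list(stages) || length(stages) == 0) {
    stopf("overall_metrics needs a non-empty list of stage_counts")
  }
  for (s in stages) stopifnot(inherits(s, "stage_counts"))
  if (length(stages) > 1) {
    for (i in seq_len(length(stages) - 1)) {
      if (stages[[i]]$actives_out != stages[[i + 1]]$actives_in ||
          stages[[i]]$decoys_out != stages[[i + 1]]$decoys_in) {
        stopf("stage chain broken between stages %d and %d", i, i + 1)
      }
    }
  }
  first <- stages[[1]]; last <- stages[[length(stages)]]
  m <- stage_metrics(stage_counts(first$actives_in, first$decoys_in,
                                  last$actives_out, last$decoys_out))
  m$ef_max <- (first$actives_in + first$decoys_in) / first$actives_in
  m$ef_pct <- 100 * m$ef / m$ef_max
  m
}

#' Round a metrics object to table-display precision
#'
#' @param m A `stage_metrics` object.
#' @param digits Decimal places (default 2, half rounded away from zero).
#' @return A named numeric vector of rounded values.
#' @export
round_metrics <- function(m, digits = 2) {
  stopifnot(inherits(m, "stage_metrics"))
  vapply(unclass(m), round_half_up, numeric(1), digits = digits)
}

#' @export
print.stage_metrics <- function(x, ...) {
  v <- round_metrics(x)
  cat("stage metrics: EF ", v[["ef"]], "  Se ", v[["se"]], "%  Sp ",
      v[["sp"]], "%", sep = "")
  if (!is.null(x$ef_max)) {
    cat("  (EF_max ", v[["ef_max"]], ", ", v[["ef_pct"]], "% of max)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.stage_counts <- function(x, ...) {
  cat(sprintf("stage counts: actives %d -> %d, decoys %d -> %d\n",
              x$actives_in, x$actives_out, x$decoys_in, x$decoys_out))
  invisible(x)
}

#' Per-stage and overall metrics table from a chain of counts
#'
#' Produces a long-format table mirroring a validation summary: one row per
#' scored stage plus an overall row. The first stage of a cascade run in
#' exclude mode (the antipharmacophore) is conventionally reported with
#' counts only; pass `score_first = FALSE` to suppress its EF/Se/Sp.
#'
#' @param stages List of [stage_counts()] in cascade order.
#' @param stage_names Optional character vector of stage names.
#' @param score_first Score the first stage too? Default `FALSE`.
#' @return A data.frame with columns stage, actives_in, decoys_in,
#'   actives_out, decoys_out, ef, se, sp (2-dp; NA where not scored).
#' @export
metrics_table <- function(stages, stage_names = NULL, score_first = FALSE) {
  n <- length(stages)
  if (is.null(stage_names)) stage_names <- paste0("stage", seq_len(n))
  stopifnot(length(stage_names) == n)
  rows <- lapply(seq_len(n), function(i) {
    s <- stages[[i]]
    scored <- score_first || i > 1
    m <- if (scored) round_metrics(stage_metrics(s)) else
      c(ef = NA_real_, se = NA_real_, sp = NA_real_)
    data.frame(stage = stage_names[i],
               actives_in = s$actives_in, decoys_in = s$decoys_in,
               actives_out = s$actives_out, decoys_out = s$decoys_out,
               ef = m[["ef"]], se = m[["se"]], sp = m[["sp"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ov <- overall_metrics(stages)
  ovr <- round_metrics(ov)
  first <- stages[[1]]; last <- stages[[n]]
  out <- rbind(out, data.frame(
    stage = "overall",
    actives_in = first$actives_in, decoys_in = first$decoys_in,
    actives_out = last$actives_out, decoys_out = last$decoys_out,
    ef = ovr[["ef"]], se = ovr[["se"]], sp = ovr[["sp"]],
    stringsAsFactors = FALSE))
  attr(out, "ef_max") <- ov$ef_max
  attr(out, "ef_pct") <- ov$ef_pct
  out
}
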