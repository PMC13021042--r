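#' Signed response offset relative to a probe
#'
#' The magnitude is the circular distance between report and target; the
#' sign is positive when the report is displaced from the target in the
#' direction of the probe. When the probe coincides with the target the
#' direction is undefined: the sign is assigned at random and a warning
#' is raised.
#'
#' @param response,S_M,S_P report, target, and reference-probe angles in
#'   degrees (vectors recycled to common length).
#' @return signed offsets in degrees, in (-180, 180].
#' @export
signed_offset <- function(response, S_M, S_P) {
  raw <- signed_circ_dist(response, S_M)
  dir <- signed_circ_dist(S_P, S_M)
  und <- dir == 0
  if (any(und)) {
    warning("undefined-direction: probe equals target on ", sum(und),
            " trial(s); sign assigned at random", call. = FALSE)
    dir[und] <- sample(c(-1, 1), sum(und), replace = TRUE)
  }
  raw * sign(dir)
}

#' @rdname signed_offset
#' @details `signed_offset_exp2()` is the 2AFC variant: identical
#'   arithmetic with the first pair's similar probe as the reference.
#' @param first_similar_probe reference probe for the 2AFC designs.
#' @export
signed_offset_exp2 <- function(response, S_M, first_similar_probe) {
  signed_offset(response, S_M, first_similar_probe)
}

#' Randomly sign baseline offset magnitudes
#'
#' Baseline trials have no probe to define a direction; their offset
#' magnitudes are given i.i.d. random signs so that baseline
#' distributions are comparable with the signed comparison-trial
#' distributions.
#'
#' @param offsets numeric offsets (any sign; magnitudes are kept).
#' @return signed offsets with random signs.
#' @export
assign_baseline_signs <- function(offsets) {
  abs(offsets) * sample(c(-1, 1), length(offsets), replace = TRUE)
}

#' Keep only high-confidence reports
#'
#' Restricts a trial table to confidence = 1 rows and records the
#' retained fraction per participant and condition in the
#' `"retention"` attribute. A participant/condition cell left empty is
#' flagged with a warning.
#'
#' @param trials trial-table data.frame with a `confidence` column.
#' @return filtered table with a `retention` attribute.
#' @export
filter_high_confidence <- function(trials) {
  stopifnot("confidence" %in% names(trials))
  keep <- trials$confidence == 1
  ret <- stats::aggregate(keep,
                          by = list(participant_id = trials$participant_id,
                                    condition = trials$condition),
                          FUN = mean)
  names(ret)[3] <- "retained"
  empty <- ret[ret$retained == 0, , drop = FALSE]
  if (nrow(empty) > 0) {
    warning("no high-confidence trials for ", nrow(empty),
            " participant x condition cell(s)", call. = FALSE)
  }
  out <- trials[keep, , drop = FALSE]
  attr(out, "retention") <- ret
  out
}

#' Per-trial signed offsets for a simulated or observed trial table
#'
#' Builds the analysis table: one row per trial with the participant,
#' condition, probe distance, first judgment, signed offset, and
#' confidence. Comparison/experimental trials are signed toward the
#' trial's reference probe (the single probe for exp1; the first pair's
#' similar probe for exp2/exp3); baseline trials get random signs.
#'
#' @param trials trial-table data.frame (schema of [generate_dataset()]).
#' @return data.frame with columns `participant_id`, `condition`,
#'   `probe_distance` (NA on baseline trials), `judgment`, `offset`,
#'   `confidence`.
#' @export
compute_offsets <- function(trials) {
  baseline <- trials$condition %in% c("baseline", "baseline_short",
                                      "baseline_long")
  off <- numeric(nrow(trials))
  pd <- rep(NA_real_, nrow(trials))
  if (any(!baseline)) {
    i <- which(!baseline)
    ref <- trials$probe1_sim[i]
    off[i] <- signed_offset(trials$response[i], trials$S_M[i], ref)
    pd[i] <- abs(signed_circ_dist(ref, trials$S_M[i]))
  }
  if (any(baseline)) {
    i <- which(baseline)
    off[i] <- assign_baseline_signs(
      signed_circ_dist(trials$response[i], trials$S_M[i]))
  }
  data.frame(participant_id = trials$participant_id,
             condition = trials$condition,
             probe_distance = pd,
             judgment = if ("judgment1" %in% names(trials))
               trials$judgment1 else NA_character_,
             offset = off,
             confidence = trials$confidence,
             stringsAsFactors = FALSE)
}

## Cohen's d for a one-sample (or paired-difference) vector.
cohens_d <- function(x) mean(x) / stats::sd(x)

#' Group-level bias summary
#'
#' Collapses per-trial signed offsets to participant means per condition
#' and runs the group-level tests: a one-sample t test of each
#' condition's mean against zero and, when `contrast` names two
#' conditions, a paired t test of their difference. Cohen's d is the
#' mean over SD of the participant means (one-sample) or of the paired
#' differences.
#'
#' @param offsets offset table from [compute_offsets()] (optionally
#'   filtered).
#' @param conditions conditions to summarize (default: all present).
#' @param contrast optional length-2 character vector of conditions to
#'   compare with a paired t test (first minus second).
#' @param absolute compare absolute participant means in the contrast
#'   (used for bias-magnitude contrasts across oppositely signed
#'   conditions).
#' @return object of class `bias_summary`: list with `participant_means`
#'   (participant x condition data.frame), `group` (per-condition stats)
#'   and optionally `contrast`.
#' @export
bias_magnitude <- function(offsets, conditions = NULL, contrast = NULL,
                           absolute = FALSE) {
  if (is.null(conditions)) conditions <- unique(offsets$condition)
  offsets <- offsets[offsets$condition %in% conditions, , drop = FALSE]
  pm <- stats::aggregate(offset ~ participant_id + condition, data = offsets,
                         FUN = mean)
  nn <- stats::aggregate(offset ~ participant_id + condition, data = offsets,
                         FUN = length)
  names(nn)[3] <- "n_trials"
  pm <- merge(pm, nn, by = c("participant_id", "condition"))

  one_sample <- function(x) {
    if (length(x) < 2) stop("insufficient-data: need >= 2 participants",
                            call. = FALSE)
    if (stats::sd(x) == 0) {
      # degenerate cell: the mean is exact, the t statistic undefined
      return(data.frame(mean = mean(x), t = NA_real_, df = length(x) - 1,
                        p = NA_real_, ci_lo = mean(x), ci_hi = mean(x),
                        d = NA_real_, n = length(x)))
    }
    tt <- stats::t.test(x)
    data.frame(mean = mean(x), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               d = cohens_d(x), n = length(x))
  }
  group <- do.call(rbind, lapply(conditions, function(cc) {
    g <- one_sample(pm$offset[pm$condition == cc])
    cbind(condition = cc, g)
  }))

  res <- list(participant_means = pm, group = group)
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2)
    a <- pm[pm$condition == contrast[1], c("participant_id", "offset")]
    b <- pm[pm$condition == contrast[2], c("participant_id", "offset")]
    m <- merge(a, b, by = "participant_id", suffixes = c("_1", "_2"))
    v1 <- if (absolute) abs(m$offset_1) else m$offset_1
    v2 <- if (absolute) abs(m$offset_2) else m$offset_2
    res$contrast <- cbind(
      data.frame(condition = paste(contrast, collapse = " - ")),
      one_sample(v1 - v2))
  }
  class(res) <- "bias_summary"
  res
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("Bias summary (participant-mean signed offsets, degrees)\n")
  g <- x$group
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-22s M = %6.2f, t(%d) = %5.2f, p = %.4g, d = %5.2f\n",
                g$condition[i], g$mean[i], g$df[i], g$t[i], g$p[i], g$d[i]))
  }
  if (!is.null(x$contrast)) {
    cc <- x$contrast
    cat(sprintf("  %-22s dM = %5.2f, t(%d) = %5.2f, p = %.4g, d = %5.2f\n",
                cc$condition, cc$mean, cc$df, cc$t, cc$p, cc$d))
  }
  invisible(x)
}

#' Discretize probe distances into equal-width bins
#'
#' @param distance unsigned probe distances in degrees.
#' @param n_bins number of bins (default 18).
#' @param range sampled range of distances.
#' @return integer bin indices 1..n_bins; bins are right-open except the
#'   last, which is closed.
#' @export
discretize_probe_distance <- function(distance, n_bins = 18,
                                      range = c(16, 105)) {
  if (any(distance < range[1] - 1e-9 | distance > range[2] + 1e-9,
          na.rm = TRUE)) {
    stop("invalid-distance: probe distance outside [",
         range[1], ", ", range[2], "]", call. = FALSE)
  }
  width <- diff(range) / n_bins
  # small forward tolerance keeps exact bin edges in their right-open bin
  b <- pmin(floor((distance - range[1]) / width + 1e-9) + 1L, n_bins)
  as.integer(b)
}

#' Ambivalent-probe analysis
#'
#' Isolates the effect of subjective similarity while holding physical
#' similarity constant: probe distances are binned, and for each
#' participant only bins that produced both a "similar" and a
#' "dissimilar" judgment on separate trials (ambivalent bins) are kept.
#' Within each ambivalent bin the mean signed offset is computed per
#' judgment type, then averaged across the participant's ambivalent
#' bins. Participants with no ambivalent bin are excluded and flagged.
#'
#' @param offsets offset table from [compute_offsets()], comparison
#'   trials with judgments.
#' @param bin_width bin width in degrees (default 5).
#' @param range sampled probe-distance range.
#' @return object of class `ambivalent_result`: data.frame with one row
#'   per retained participant (`bias_similar`, `bias_dissimilar`,
#'   `difference`, `n_bins`), with excluded participants in the
#'   `"excluded"` attribute.
#' @export
ambivalent_probe_analysis <- function(offsets, bin_width = 5,
                                      range = c(16, 105)) {
  x <- offsets[!is.na(offsets$probe_distance) &
                 offsets$judgment %in% c("similar", "dissimilar"), ,
               drop = FALSE]
  n_bins <- ceiling(diff(range) / bin_width)
  # bins of exactly bin_width degrees, the last padded to cover the range
  x$bin <- discretize_probe_distance(x$probe_distance, n_bins,
                                     c(range[1], range[1] + n_bins * bin_width))
  res <- list()
  excluded <- integer(0)
  for (p in unique(x$participant_id)) {
    xp <- x[x$participant_id == p, ]
    cell <- stats::aggregate(offset ~ bin + judgment, data = xp, FUN = mean)
    tab <- table(cell$bin)
    amb <- as.integer(names(tab)[tab == 2])
    if (length(amb) == 0) {
      excluded <- c(excluded, p)
      next
    }
    sim <- cell$offset[cell$judgment == "similar" & cell$bin %in% amb]
    dis <- cell$offset[cell$judgment == "dissimilar" & cell$bin %in% amb]
    res[[length(res) + 1]] <- data.frame(
      participant_id = p, n_bins = length(amb),
      bias_similar = mean(sim), bias_dissimilar = mean(dis),
      difference = mean(sim) - mean(dis))
  }
  if (length(excluded)) {
    warning(length(excluded), " participant(s) had no ambivalent bins and ",
            "were excluded", call. = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(participant_id = integer(0), n_bins = integer(0),
               bias_similar = numeric(0), bias_dissimilar = numeric(0),
               difference = numeric(0))
  attr(out, "excluded") <- excluded
  class(out) <- c("ambivalent_result", class(out))
  out
}

#' Smoothed signed-offset distributions per condition
#'
#' Per-degree response proportions of signed offsets per participant and
#' condition, averaged across participants, then box-smoothed with
#' [smooth_circular()]. Within-subject standard errors use the
#' Cousineau-Morey normalization (participant effects removed, variance
#' rescaled by C/(C-1) over the C conditions).
#'
#' @param offsets offset table from [compute_offsets()].
#' @param window smoothing window in degrees.
#' @return data.frame with columns `condition`, `offset` (-180..179),
#'   `proportion`, `sem_ws`.
#' @export
offset_distribution <- function(offsets, window = 30) {
  bins <- -180:179
  conds <- unique(offsets$condition)
  parts <- unique(offsets$participant_id)
  # per-participant x condition per-bin proportions
  arr <- array(0, dim = c(length(parts), length(conds), length(bins)),
               dimnames = list(parts, conds, bins))
  for (i in seq_along(parts)) for (j in seq_along(conds)) {
    o <- offsets$offset[offsets$participant_id == parts[i] &
                          offsets$condition == conds[j]]
    if (!length(o)) next
    idx <- ((round(o) + 180) %% 360) + 1
    tab <- tabulate(idx, nbins = 360)
    arr[i, j, ] <- tab / sum(tab)
  }
  # Cousineau-Morey: remove each participant's overall mean profile
  pmean <- apply(arr, c(1, 3), mean)
  gmean <- apply(arr, 3, mean)
  norm <- arr
  for (j in seq_along(conds)) {
    norm[, j, ] <- arr[, j, ] - pmean + rep(gmean, each = length(parts))
  }
  cfac <- if (length(conds) > 1) length(conds) / (length(conds) - 1) else 1
  out <- lapply(seq_along(conds), function(j) {
    m <- apply(arr[, j, , drop = FALSE], 3, mean)
    se <- sqrt(cfac * apply(norm[, j, , drop = FALSE], 3, stats::var) /
                 length(parts))
    data.frame(condition = conds[j], offset = bins,
               proportion = smooth_circular(m, window),
               sem_ws = smooth_circular(se, window))
  })
  do.call(rbind, out)
}
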