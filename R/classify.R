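# FSI / NFSI classification from the three discriminative waveform features.

#' Default three-feature classification rule
#'
#' Midpoint thresholds between the two class means for AHP depth, spike
#' duration increase, and spike amplitude reduction. A cell votes FSI on a
#' feature when its value lies on the FSI side of the midpoint (deeper AHP,
#' smaller duration increase, smaller amplitude reduction).
#'
#' @param margin half-width (in each feature's own units) of the uncertainty
#'   band around each threshold; a feature inside the band casts no vote.
#' @return a list of class `ng2_class_rule`.
#' @export
default_class_rule <- function(margin = 0) {
  check_that(margin >= 0, "margin must be >= 0")
  structure(
    list(
      thresholds = c(
        ahp = (-15.89 + -8.43) / 2,             # FSI if <= -12.16
        dur_increase = (6.79 + 55.06) / 2,      # FSI if <= 30.925
        amp_reduction = (-0.24 + 7.59) / 2      # FSI if <= 3.675
      ),
      margin = margin
    ),
    class = "ng2_class_rule"
  )
}

#' Classify an interneuron as FSI, NFSI or ambiguous
#'
#' Each of the three discriminative features casts a vote (FSI side vs NFSI
#' side of its midpoint threshold); features within `margin` of their
#' threshold, or missing, abstain. The label is the side with at least two
#' definite votes; anything else (including any missing required feature)
#' is `"ambiguous"`.
#'
#' @param fs an `ng2_feature_set` (or named list with `ahp`, `dur_increase`,
#'   `amp_reduction`).
#' @param rule an `ng2_class_rule`, default [default_class_rule()].
#' @return character scalar: `"FSI"`, `"NFSI"` or `"ambiguous"`, with the
#'   per-feature votes attached as attribute `votes`.
#' @export
classify_interneuron <- function(fs, rule = default_class_rule()) {
  feats <- c("ahp", "dur_increase", "amp_reduction")
  vals <- vapply(feats, function(f) {
    v <- fs[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  votes <- character(3)
  names(votes) <- feats
  for (i in seq_along(feats)) {
    v <- vals[i]
    thr <- rule$thresholds[[feats[i]]]
    if (!is.finite(v) || abs(v - thr) <= rule$margin) {
      votes[i] <- "abstain"
    } else {
      # all three features: FSI lies below the midpoint
      votes[i] <- if (v < thr) "FSI" else "NFSI"
    }
  }
  n_fsi <- sum(votes == "FSI")
  n_nfsi <- sum(votes == "NFSI")
  label <- if (n_fsi >= 2 && n_fsi > n_nfsi) "FSI"
    else if (n_nfsi >= 2 && n_nfsi > n_fsi) "NFSI"
    else "ambiguous"
  structure(label, votes = votes)
}

#' Extract features and classify a synthetic cohort
#'
#' Convenience wrapper used by the pipeline and the recovery tests: generates
#' `n_per_class` cells per class, runs the extraction pipeline and the
#' classifier, and tabulates recovered vs true labels.
#'
#' @param n_per_class cells per class.
#' @param seed integer seed.
#' @param fsi,nfsi class parameter objects.
#' @param rule classification rule.
#' @return a data.frame with one row per cell: true label, assigned label,
#'   and the 19 extracted features.
#' @export
classify_cohort <- function(n_per_class = 100, seed = 1,
                            fsi = fsi_params(), nfsi = nfsi_params(),
                            rule = default_class_rule()) {
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2, 2 * n_per_class)
    rows <- vector("list", 2 * n_per_class)
    for (i in seq_len(2 * n_per_class)) {
      params <- if (i <= n_per_class) fsi else nfsi
      cell <- gen_interneuron_cell(params, seed = seeds[i])
      fs <- extract_feature_set(cell$traces, cell$protocols)
      rows[[i]] <- data.frame(
        true_label = params$label,
        label = as.character(classify_interneuron(fs, rule)),
        as.data.frame(unclass(fs)[names(fs)])
      )
    }
    do.call(rbind, rows)
  })
}
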