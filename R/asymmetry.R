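# Left/right asymmetry features and the five feature-set variants:
# left, right, whole, difference, ratio.

#' Difference asymmetry feature
#'
#' `|left - right|` by default; the signed raw form `left - right` is
#' available with `absolute = FALSE`.
#'
#' @param left,right Finite numeric vectors (recycled pairwise).
#' @param absolute Use the absolute value (default `TRUE`).
#' @return Numeric vector of differences.
#' @export
difference_feature <- function(left, right, absolute = TRUE) {
  abort_if(!all(is.finite(left)) || !all(is.finite(right)),
           "difference_feature requires finite inputs")
  d <- left - right
  if (absolute) abs(d) else d
}

#' Ratio asymmetry feature
#'
#' `left / right`; denominators with `|right| <= eps` are degenerate and
#' raise an error (callers drop such columns instead of imputing).
#'
#' @param left,right Finite numeric vectors.
#' @param eps Degeneracy threshold for the denominator (default 1e-12).
#' @return Numeric vector of ratios.
#' @export
ratio_feature <- function(left, right, eps = 1e-12) {
  abort_if(!all(is.finite(left)) || !all(is.finite(right)),
           "ratio_feature requires finite inputs")
  abort_if(any(abs(right) <= eps), "degenerate ratio denominator")
  left / right
}

#' Build one feature-set variant from a per-hemisphere feature table
#'
#' Variants: `left` / `right` keep only that hemisphere's columns; `whole`
#' concatenates both; `difference` and `ratio` produce one column per matched
#' left/right pair, named `{structure}_diff_{family}_{feature}` or
#' `{structure}_ratio_{family}_{feature}`. Ratio columns whose denominator is
#' degenerate for any subject are dropped with a warning. Column order is
#' deterministic (structure, family, feature).
#'
#' @param features Cohort feature tibble from [extract_features()]
#'   (`subject_id`, `class`, paired `*_left_*` / `*_right_*` columns).
#' @param variant One of `"left"`, `"right"`, `"whole"`, `"difference"`,
#'   `"ratio"`.
#' @param absolute Difference variant: absolute (default) or signed.
#' @param eps Ratio degeneracy threshold.
#' @return A tibble `subject_id`, `class`, variant feature columns, with the
#'   variant recorded in attribute `variant`.
#' @export
build_variant <- function(features,
                          variant = c("whole", "left", "right",
                                      "difference", "ratio"),
                          absolute = TRUE, eps = 1e-12) {
  variant <- match.arg(variant)
  cols <- feature_columns(features)
  meta <- feature_metadata(cols)
  abort_if(!all(meta$hemisphere %in% HEMISPHERES),
           "build_variant expects per-hemisphere feature columns")
  meta <- meta[order(meta$structure, meta$family, meta$feature,
                     meta$hemisphere), ]
  pick <- function(h) meta$name[meta$hemisphere == h]
  out <- features[c("subject_id", "class")]
  if (variant %in% c("left", "right")) {
    out <- dplyr::bind_cols(out, features[pick(variant)])
  } else if (variant == "whole") {
    out <- dplyr::bind_cols(out, features[c(pick("left"), pick("right"))])
  } else {
    lm <- meta[meta$hemisphere == "left", ]
    for (i in seq_len(nrow(lm))) {
      rname <- sub("_left_", "_right_", lm$name[i], fixed = TRUE)
      abort_if(!rname %in% cols,
               paste0("unmatched left/right pair for ", lm$name[i]))
      tag <- if (variant == "difference") "diff" else "ratio"
      new <- paste(lm$structure[i], tag, lm$family[i], lm$feature[i],
                   sep = "_")
      if (variant == "difference") {
        out[[new]] <- difference_feature(features[[lm$name[i]]],
                                         features[[rname]],
                                         absolute = absolute)
      } else {
        if (any(abs(features[[rname]]) <= eps)) {
          warning("dropping ratio column ", new,
                  ": degenerate denominator for some subject", call. = FALSE)
          next
        }
        out[[new]] <- ratio_feature(features[[lm$name[i]]],
                                    features[[rname]], eps = eps)
      }
    }
  }
  attr(out, "variant") <- variant
  out
}
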