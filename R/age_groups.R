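#' Stand age groups and their indicator coding
#'
#' Chinese fir stands are classified into five developmental stages. For
#' dummy-variable modelling each stage is coded by a 4-vector of indicators
#' (Q1..Q4) with the over-mature stage as the all-zero reference:
#' young = (1,0,0,0), middle-aged = (0,1,0,0), near-mature = (0,0,1,0),
#' mature = (0,0,0,1), over-mature = (0,0,0,0).
#'
#' @return Character vector of the five age-group labels, in developmental
#'   order.
#' @examples
#' age_group_labels()
#' @export
age_group_labels <- function() {
  c("young", "middle_aged", "near_mature", "mature", "over_mature")
}

#' Indicator (dummy) codes for age groups
#'
#' @param groups Character or factor vector of age-group labels.
#' @return A numeric matrix with one row per element of `groups` and columns
#'   `Q1`..`Q4`; rows follow the coding described in [age_group_labels()].
#' @examples
#' age_group_dummies(c("young", "over_mature"))
#' @export
age_group_dummies <- function(groups) {
  labels <- age_group_labels()
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), labels)
  if (length(bad)) {
    stop("unknown age-group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  codes <- rbind(
    young       = c(1, 0, 0, 0),
    middle_aged = c(0, 1, 0, 0),
    near_mature = c(0, 0, 1, 0),
    mature      = c(0, 0, 0, 1),
    over_mature = c(0, 0, 0, 0)
  )
  colnames(codes) <- paste0("Q", 1:4)
  out <- codes[groups, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Observed per-group envelopes (min/max over all surveyed plots) for stand
## density (trees/hm^2), quadratic-mean DBH (cm) and mean height (m). The
## generator draws stand attributes inside these ranges.
age_group_envelopes <- function() {
  env <- list(
    young       = list(density = c(2100, 5311), dbh = c(6.1, 15.3), height = c(5.0, 11.8)),
    middle_aged = list(density = c(844, 4355),  dbh = c(9.2, 22.8), height = c(6.9, 16.7)),
    near_mature = list(density = c(1267, 3711), dbh = c(11.0, 18.8), height = c(6.4, 14.5)),
    mature      = list(density = c(911, 3244),  dbh = c(13.3, 26.2), height = c(8.6, 21.3)),
    over_mature = list(density = c(433, 2856),  dbh = c(13.4, 28.2), height = c(8.8, 20.0))
  )
  env
}

#' Attribute envelope for one age group
#'
#' Min--max ranges of stand density (trees/hm^2), quadratic mean DBH (cm) and
#' mean height (m) observed for the stage, used by [generate_stand()] to draw
#' stand attributes.
#'
#' @param age_group One age-group label.
#' @return A list with numeric length-2 elements `density`, `dbh`, `height`.
#' @export
age_group_envelope <- function(age_group) {
  age_group <- match.arg(age_group, age_group_labels())
  age_group_envelopes()[[age_group]]
}
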