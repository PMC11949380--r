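#' Education weights for direct standardization
#'
#' A fixed education distribution (`basic`, `secondary`, `tertiary`) used
#' to recompute transition probabilities under a counterfactual, constant
#' educational composition.
#'
#' @param basic,secondary,tertiary non-negative proportions summing to 1.
#' @param provenance optional tag describing where the weights come from
#'   (e.g. the pooled observation window).
#' @return An object of class `education_weights`.
#' @export
education_weights <- function(basic, secondary, tertiary,
                              provenance = NA_character_) {
  w <- c(basic = basic, secondary = secondary, tertiary = tertiary)
  if (any(w < 0)) stop("education weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-12) stop("education weights must sum to 1 within 1e-12")
  structure(w, provenance = provenance, class = "education_weights")
}

#' @export
print.education_weights <- function(x, ...) {
  cat("Education weights:",
      paste(sprintf("%s %.4f", names(unclass(x)), unclass(x)), collapse = ", "),
      "\n")
  if (!is.na(attr(x, "provenance"))) cat("Provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Pooled education distribution of the observation window
#'
#' Person-period share of each education level pooled over the whole
#' window (all periods together) — the fixed composition used for the
#' education-adjusted counterfactual trends.
#'
#' @param data a person-period panel or `transition_counts`.
#' @return An [education_weights()] object tagged with the pooled window.
#' @export
pooled_education_weights <- function(data) {
  counts <- as_transition_counts(data, attr(data, "grid") %||% age_grid())
  if (nrow(counts) == 0L || sum(counts$n) == 0L) stop("no observations")
  tot <- tapply(counts$n, counts$education, sum)
  tot[is.na(tot)] <- 0
  w <- tot / sum(tot)
  education_weights(
    basic = unname(w["basic"]), secondary = unname(w["secondary"]),
    tertiary = unname(w["tertiary"]),
    provenance = paste("pooled person-period shares,",
                       paste(range(period_labels()), collapse = " to "))
  )
}

#' Education-standardized transition probabilities
#'
#' Entrywise mixture of education-specific transition probabilities under a
#' fixed education distribution:
#' `p_adj(age, i -> j) = sum_e w_e * p_e(age, i -> j)`.
#' A convex combination of row-stochastic matrices is row-stochastic, so
#' the result is a valid `transition_probs`. All inputs must share the same
#' grid and period context.
#'
#' @param probs_by_education named list (`basic`, `secondary`, `tertiary`)
#'   of `transition_probs` for one period and gender context.
#' @param weights an [education_weights()] object.
#' @return A `transition_probs` with the mixture probabilities; its
#'   subgroup label is marked `edu-standardized`.
#' @export
standardize_transition_probs <- function(probs_by_education, weights) {
  lev <- education_levels()
  if (!all(lev %in% names(probs_by_education))) {
    stop("probs_by_education must be a named list with elements ",
         paste(lev, collapse = ", "))
  }
  stopifnot(inherits(weights, "education_weights"))
  ref <- probs_by_education[[lev[1]]]
  for (e in lev[-1]) {
    tp <- probs_by_education[[e]]
    if (!inherits(tp, "transition_probs")) stop("element ", e, " is not transition_probs")
    if (!identical(tp$grid$points, ref$grid$points)) {
      stop("education-specific probabilities are on different grids")
    }
    if (!identical(tp$period, ref$period)) {
      stop("education-specific probabilities are for different periods (",
           tp$period, " vs ", ref$period, ")")
    }
  }
  w <- unclass(weights)
  p <- w["basic"] * probs_by_education$basic$p +
    w["secondary"] * probs_by_education$secondary$p +
    w["tertiary"] * probs_by_education$tertiary$p
  # mixing can leave ~1e-16 row-sum noise; re-normalize transient rows exactly
  for (org in c("FREE", "CVD")) {
    rs <- rowSums(p[, org, ])
    p[, org, ] <- p[, org, ] / rs
  }
  p[, "CVD", "FREE"] <- 0
  p[, "DEAD", ] <- 0
  p[, "DEAD", "DEAD"] <- 1
  base <- sub(":(basic|secondary|tertiary)$", "", ref$subgroup)
  transition_probs(p, grid = ref$grid, period = ref$period,
                   subgroup = paste0(base, ":edu-standardized"))
}
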