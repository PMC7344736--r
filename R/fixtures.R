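#' Built-in model inputs for the adjuvant-trastuzumab case study
#'
#' Returns the published model inputs of the real-world cost-effectiveness
#' analysis of one-year adjuvant trastuzumab in HER2-positive early breast
#' cancer (Cyprus NHS payer perspective) as ready-to-run objects: observed
#' transition counts and printed transition probabilities for the control
#' arm, the pooled trastuzumab arm and the three treatment subgroups; total
#' and component treatment costs with standard deviations; EQ-5D utilities;
#' discount rates; willingness-to-pay thresholds; arm sizes; and the
#' published per-strategy QALY totals (used as inputs to ICER arithmetic,
#' not reproduced by the engine).
#'
#' Arms: \code{control} (chemotherapy alone, n = 30), \code{trastuzumab}
#' (all trastuzumab arms pooled, n = 148), \code{anthracycline_trastuzumab}
#' (n = 38), \code{no_anthracycline_trastuzumab} (n = 14),
#' \code{anthracycline_taxane_trastuzumab} (n = 96).
#'
#' @return A list with components \code{counts} (named list of
#'   \code{\link{transition_counts}}), \code{printed_tp} (named list of
#'   3-decimal printed probability matrices), \code{costs} (named vector of
#'   total upfront costs, EUR), \code{cost_sd} (their SDs),
#'   \code{cost_components} (per-arm main/second gamma components and the
#'   second-component fraction), \code{utilities}
#'   (\code{\link{utility_set}}), \code{discount}
#'   (\code{\link{discount_spec}}), \code{thresholds} (EUR/QALY),
#'   \code{arm_sizes}, \code{follow_up_years} and \code{reported_qalys}
#'   (per horizon).
#' @examples
#' inp <- trastuzumab_inputs()
#' estimate_transition_matrix(inp$counts$control)
#' @export
trastuzumab_inputs <- function() {
  space <- state_space()
  mk <- function(st, rec, met, arm) {
    transition_counts(rbind(stable = st, recurrence = rec, metastasis = met,
                            death = c(0, 0, 0, 0)),
                      arm = arm, space = space)
  }
  counts <- list(
    control = mk(c(58, 3, 9, 8), c(3, 0, 0, 0), c(9, 0, 0, 0), "control"),
    trastuzumab = mk(c(400, 6, 16, 1), c(5, 1, 1, 0), c(8, 0, 5, 1),
                     "trastuzumab"),
    anthracycline_trastuzumab =
      mk(c(98, 4, 4, 0), c(3, 0, 1, 0), c(3, 0, 1, 0),
         "anthracycline_trastuzumab"),
    no_anthracycline_trastuzumab =
      mk(c(37, 1, 1, 0), c(1, 0, 0, 0), c(0, 0, 2, 0),
         "no_anthracycline_trastuzumab"),
    anthracycline_taxane_trastuzumab =
      mk(c(265, 1, 11, 1), c(1, 1, 0, 0), c(5, 0, 2, 1),
         "anthracycline_taxane_trastuzumab"))

  tp <- function(st, rec, met) {
    rbind(stable = st, recurrence = rec, metastasis = met,
          death = c(0, 0, 0, 1))
  }
  printed_tp <- list(
    control = tp(c(0.744, 0.038, 0.115, 0.103), c(1, 0, 0, 0), c(1, 0, 0, 0)),
    trastuzumab = tp(c(0.946, 0.014, 0.038, 0.002), c(0.714, 0.143, 0.143, 0),
                     c(0.571, 0, 0.357, 0.072)),
    anthracycline_trastuzumab =
      tp(c(0.925, 0.038, 0.038, 0), c(0.750, 0, 0.250, 0),
         c(0.750, 0, 0.250, 0)),
    no_anthracycline_trastuzumab =
      tp(c(0.949, 0.026, 0.026, 0), c(1, 0, 0, 0), c(0, 0, 1, 0)),
    anthracycline_taxane_trastuzumab =
      tp(c(0.953, 0.004, 0.040, 0.004), c(0.500, 0.500, 0, 0),
         c(0.625, 0, 0.250, 0.125)))

  costs <- c(control = 3978.18, trastuzumab = 45420.45,
             anthracycline_trastuzumab = 41308.19,
             no_anthracycline_trastuzumab = 43664.83,
             anthracycline_taxane_trastuzumab = 47304.25)
  cost_sd <- c(control = 1763.79, trastuzumab = 7182.79,
               anthracycline_trastuzumab = 5588.75,
               no_anthracycline_trastuzumab = 6672.79,
               anthracycline_taxane_trastuzumab = 7125.32)
  # main component: examinations + 1st chemotherapy; second component: 2nd
  # chemotherapy (control, incurred by 7 of 30 patients) or the trastuzumab
  # course (all patients of a trastuzumab arm)
  cost_components <- list(
    control = list(main = c(2786.90, 604.85), second = c(5105.47, 238.88),
                   second_fraction = 7 / 30),
    trastuzumab = list(main = c(2632.91, 905.46), second = c(38069.95, 6226.03),
                       second_fraction = 1),
    anthracycline_trastuzumab =
      list(main = c(3097.47, 396.03), second = c(38210.71, 5499.80),
           second_fraction = 1),
    no_anthracycline_trastuzumab =
      list(main = c(182.14, 63.87), second = c(37240.37, 6380.80),
           second_fraction = 1),
    anthracycline_taxane_trastuzumab =
      list(main = c(2806.43, 452.88), second = c(38135.20, 6520.39),
           second_fraction = 1))

  reported_qalys <- list(
    y20 = c(control_pooled = 1.70, trastuzumab = 2.72,
            control = 1.42, anthracycline_trastuzumab = 3.46,
            no_anthracycline_trastuzumab = 3.14,
            anthracycline_taxane_trastuzumab = 3.21),
    lifetime = c(control_pooled = 1.82, trastuzumab = 4.15,
                 control = 1.51, anthracycline_trastuzumab = 5.68,
                 no_anthracycline_trastuzumab = 4.46,
                 anthracycline_taxane_trastuzumab = 4.82))

  list(counts = counts, printed_tp = printed_tp, costs = costs,
       cost_sd = cost_sd, cost_components = cost_components,
       utilities = utility_set(), discount = discount_spec(),
       thresholds = c(20000, 40000, 60000),
       arm_sizes = c(control = 30L, trastuzumab = 148L,
                     anthracycline_trastuzumab = 38L,
                     no_anthracycline_trastuzumab = 14L,
                     anthracycline_taxane_trastuzumab = 96L),
       follow_up_years = 8L,
       reported_qalys = reported_qalys)
}

#' Build strategy objects from the case-study inputs
#'
#' @param inputs A \code{\link{trastuzumab_inputs}} list.
#' @param arms \code{"pooled"} (control vs all trastuzumab arms) or
#'   \code{"subgroups"} (control vs the three treatment subgroups), or a
#'   character vector of arm names (the first becomes the reference).
#' @param matrices \code{"estimated"} (row-normalised observed counts, the
#'   default) or \code{"printed"} (the published 3-decimal probabilities,
#'   renormalised where rounding left a row sum off 1).
#' @return A list of \code{\link{strategy}} objects suitable for
#'   \code{\link{cea_model}}.
#' @examples
#' inp <- trastuzumab_inputs()
#' mod <- cea_model(trastuzumab_strategies(inp, arms = "subgroups"))
#' summary(mod)
#' @export
trastuzumab_strategies <- function(inputs = trastuzumab_inputs(),
                                   arms = c("pooled", "subgroups"),
                                   matrices = c("estimated", "printed")) {
  matrices <- match.arg(matrices)
  if (length(arms) == 1L && arms %in% c("pooled", "subgroups")) {
    arms <- if (arms == "pooled") c("control", "trastuzumab")
    else c("control", "anthracycline_trastuzumab",
           "no_anthracycline_trastuzumab", "anthracycline_taxane_trastuzumab")
  }
  if (!all(arms %in% names(inputs$counts))) {
    stop("unknown arm(s): ",
         paste(setdiff(arms, names(inputs$counts)), collapse = ", "),
         call. = FALSE)
  }
  lapply(arms, function(a) {
    m <- if (matrices == "estimated") {
      estimate_transition_matrix(inputs$counts[[a]])
    } else {
      suppressMessages(transition_matrix(inputs$printed_tp[[a]], arm = a))
    }
    strategy(a, m, upfront_cost = inputs$costs[[a]],
             cost_sd = inputs$cost_sd[[a]],
             n_patients = inputs$arm_sizes[[a]])
  })
}

#' Aggregate an arm's mean total cost from its components
#'
#' Mean total upfront cost = main-component mean + second-component fraction
#' times second-component mean. For the control arm this reproduces the
#' published total (2786.90 + (7/30) x 5105.47 = 3978.18 EUR).
#'
#' @param components One element of
#'   \code{trastuzumab_inputs()$cost_components}: list with \code{main},
#'   \code{second} (each \code{c(mean, sd)} or NULL) and
#'   \code{second_fraction}.
#' @return Mean total cost (EUR).
#' @export
aggregate_cost <- function(components) {
  total <- components$main[1L]
  if (!is.null(components$second)) {
    total <- total + components$second_fraction * components$second[1L]
  }
  total
}
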