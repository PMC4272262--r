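# Model discrimination: score candidate structural models against the
# observed hydrodynamic and spectroscopic quantities.

#' Compare predicted model properties with observations
#'
#' Each candidate model's predictions are compared with the observed
#' values property by property. A prediction is \code{"consistent"}
#' with an observation when |predicted - observed| <= tolerance for
#' that property; the total score is the sum of |predicted - observed|
#' / tolerance over the properties available, so the ranking is
#' invariant to uniform rescaling of all tolerances. Ties are broken by
#' model id.
#'
#' @param predicted data.frame with a \code{model_id} column and one
#'   column per predicted property (\code{s20w}, \code{rho_ns},
#'   \code{cd_amplitude_ratio}, ...).
#' @param observed named list/vector of observed values for (a subset
#'   of) the same properties.
#' @param tolerances named vector of per-property agreement tolerances;
#'   defaults: 0.1 S for \code{s20w} (the spread of ensemble bead-shell
#'   predictions), 4.1 ns for \code{rho_ns} (the experimental
#'   uncertainty), 0.5 for \code{cd_amplitude_ratio}.
#' @param score \code{"absolute"} (default, sum of scaled absolute
#'   deviations) or \code{"chisq"} (sum of squared scaled deviations).
#' @return data.frame ranked by ascending score: model_id, one
#'   \code{dev_*} and \code{ok_*} column per scored property, score,
#'   consistent (all properties within tolerance) and rank. Properties
#'   predicted but not observed are skipped with a warning, never
#'   imputed.
#' @examples
#' pred <- data.frame(model_id = c("stacked", "beads", "hybrid"),
#'                    s20w = c(4.00, 3.1, 3.2))
#' compareModels(pred, c(s20w = 4.05))
#' @export
compareModels <- function(predicted,
                          observed,
                          tolerances = c(s20w = 0.1, rho_ns = 4.1,
                                         cd_amplitude_ratio = 0.5),
                          score = c("absolute", "chisq")) {
  score <- match.arg(score)
  if (!nrow(predicted)) stop("no models supplied")
  if (!"model_id" %in% names(predicted))
    stop("predicted must have a model_id column")
  props <- setdiff(names(predicted), "model_id")
  obs <- unlist(observed)
  missing_obs <- setdiff(props, names(obs))
  if (length(missing_obs)) {
    warning("no observed value for: ", paste(missing_obs, collapse = ", "),
            "; these properties are skipped, not imputed")
    props <- setdiff(props, missing_obs)
  }
  if (!length(props)) stop("no property is both predicted and observed")
  no_tol <- setdiff(props, names(tolerances))
  if (length(no_tol))
    stop("no tolerance given for: ", paste(no_tol, collapse = ", "))
  out <- data.frame(model_id = predicted$model_id)
  total <- rep(0, nrow(predicted))
  allok <- rep(TRUE, nrow(predicted))
  for (p in props) {
    dev <- predicted[[p]] - obs[[p]]
    scaled <- abs(dev) / tolerances[[p]]
    out[[paste0("dev_", p)]] <- dev
    out[[paste0("ok_", p)]] <- abs(dev) <= tolerances[[p]] + 1e-12
    total <- total + if (score == "absolute") scaled else scaled^2
    allok <- allok & out[[paste0("ok_", p)]]
  }
  out$score <- total
  out$consistent <- allok
  o <- order(out$score, as.character(out$model_id))
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize sedimentation shifts of mutant sequences
#'
#' @param wt wild-type s20,w (Svedberg, > 0).
#' @param mutants numeric vector of mutant s20,w values (> 0), optionally
#'   named.
#' @param sd measurement standard deviation used for the significance
#'   classification (default 0.04 S).
#' @return data.frame with per-mutant \code{delta_s} (mutant - wt) and a
#'   \code{classification}: \code{"expanded"} when delta_s < -2 sd
#'   (slower, hydrodynamically expanded), \code{"compacted"} when
#'   delta_s > 2 sd, else \code{"unchanged"}; plus a \code{mean_delta}
#'   attribute.
#' @examples
#' mutantShiftReport(4.05, c(m1 = 3.5, m2 = 3.55, m3 = 3.6))
#' @export
mutantShiftReport <- function(wt, mutants, sd = 0.04) {
  if (wt <= 0 || any(mutants <= 0))
    stop("sedimentation coefficients must be > 0")
  nm <- names(mutants)
  if (is.null(nm)) nm <- paste0("mutant", seq_along(mutants))
  ds <- mutants - wt
  cls <- ifelse(ds < -2 * sd, "expanded",
                ifelse(ds > 2 * sd, "compacted", "unchanged"))
  out <- data.frame(mutant = nm, s20w = unname(mutants),
                    delta_s = unname(ds), classification = unname(cls))
  attr(out, "mean_delta") <- mean(ds)
  out
}
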