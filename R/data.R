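# Validation of dose-response observation tables.  All user-facing fitting
# functions funnel through here so that downstream code can rely on the
# standard columns: dose, response (plus successes/total for binomial data),
# weight, curve.

validate_dr_data <- function(data,
                             response_type = c("continuous", "binomial",
                                               "poisson")) {
  response_type <- match.arg(response_type)
  if (!is.data.frame(data)) stop("'data' must be a data frame", call. = FALSE)
  data <- tibble::as_tibble(data)
  if (!"dose" %in% names(data)) {
    stop("'data' must contain a 'dose' column", call. = FALSE)
  }
  if (nrow(data) == 0) stop("'data' has no observations", call. = FALSE)
  if (any(!is.finite(data$dose)) || any(data$dose < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }

  if (response_type == "continuous") {
    if (!"response" %in% names(data)) {
      stop("continuous data must contain a 'response' column", call. = FALSE)
    }
    if (any(!is.finite(data$response))) {
      stop("responses must be finite", call. = FALSE)
    }
  } else if (response_type == "binomial") {
    if (!all(c("successes", "total") %in% names(data))) {
      stop("binomial data must contain 'successes' and 'total' columns",
           call. = FALSE)
    }
    if (any(data$total < 1) || any(data$successes < 0) ||
        any(data$successes > data$total)) {
      stop("binomial data require 0 <= successes <= total, total >= 1",
           call. = FALSE)
    }
    data$response <- data$successes / data$total
  } else {
    if ("count" %in% names(data) && !"response" %in% names(data)) {
      data$response <- data$count
    }
    if (!"response" %in% names(data)) {
      stop("count data must contain a 'count' (or 'response') column",
           call. = FALSE)
    }
    if (any(data$response < 0) || any(data$response != round(data$response))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
  }

  if (!"weight" %in% names(data)) data$weight <- 1
  if (any(!is.finite(data$weight)) || any(data$weight <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (!"curve" %in% names(data)) data$curve <- "1"
  data$curve <- as.character(data$curve)
  data
}

# per-dose mean responses (within one curve), sorted by dose
dose_means <- function(data) {
  agg <- stats::aggregate(response ~ dose, data = data, FUN = mean)
  agg[order(agg$dose), ]
}
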