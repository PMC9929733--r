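.datatable.aware <- TRUE

`%||%` <- function(x, y) if (is.null(x)) y else x

bg_error <- function(msg, class) {
  stop(structure(class = c(class, "bg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

config_error <- function(field, msg) {
  bg_error(sprintf("invalid configuration field '%s': %s", field, msg),
           "bg_config_error")
}

validation_error <- function(msg) bg_error(msg, "bg_validation_error")

contract_error <- function(msg) bg_error(msg, "bg_contract_error")

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a single finite number")
  if (integer && x != round(x))
    config_error(field, "must be an integer")
  if (x < lower || x > upper)
    config_error(field, sprintf("must be in [%s, %s]", lower, upper))
  invisible(x)
}

#' @noRd
stratum_levels <- function() c("low", "medium", "high", "very_high")

exclusion_levels <- function() {
  c("none", "duplicate_block", "adjacency_90min", "no_target_gt_10h")
}
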