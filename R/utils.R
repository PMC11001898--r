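#' @importFrom stats median quantile sd var rnorm runif rbinom rgamma rnbinom
#'   rlnorm rchisq pchisq pf pt qnorm setNames aggregate p.adjust shapiro.test
#'   wilcox.test cor aov anova complete.cases
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom methods is as
NULL

.lungspan_env <- new.env(parent = emptyenv())
.lungspan_env$quiet <- FALSE

#' Suppress or restore progress messages
#'
#' All informational messages go to stderr via [message()]; this switch mutes
#' them package-wide (warnings and errors are unaffected).
#'
#' @param quiet logical; `TRUE` silences log messages.
#' @return The previous value, invisibly.
#' @export
ls_quiet <- function(quiet = TRUE) {
  old <- .lungspan_env$quiet
  .lungspan_env$quiet <- isTRUE(quiet)
  invisible(old)
}

ls_log <- function(...) {
  if (!isTRUE(.lungspan_env$quiet)) message("[lungspan] ", ...)
}

#' Ordered life-stage group labels
#'
#' The five ordered groups span development (T1-T3: first/second/last
#' trimester equivalents) and adulthood (T4: non-aging adult, T5: aging
#' adult), with total order T1 < T2 < ... < T5.
#'
#' @return Character vector `c("T1","T2","T3","T4","T5")`.
#' @export
group_levels <- function() paste0("T", 1:5)

as_group_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), group_levels())
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(group_levels(), collapse = ", "), ")")
  }
  factor(as.character(x), levels = group_levels(), ordered = TRUE)
}

# stable seed derivation for sub-streams; keeps results < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629L)
}
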