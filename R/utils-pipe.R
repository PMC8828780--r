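#' Pipe operator
#'
#' Re-exported from dplyr (magrittr).
#'
#' @name %>%
#' @rdname pipe
#' @keywords internal
#' @importFrom dplyr %>%
#' @export
#' @usage lhs \%>\% rhs
NULL
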