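#' @importFrom rlang %||%
#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

# safe named-vector lookup with default
vget <- function(v, nm, default = 0) {
  if (!is.null(names(v)) && nm %in% names(v)) unname(v[[nm]]) else default
}
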