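#' @importFrom rlang .data
NULL

.onLoad <- function(libname, pkgname) {
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    registerS3method("autoplot", "diet_eval", plot_eval,
                     envir = asNamespace("ggplot2"))
  }
}
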