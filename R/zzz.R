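#' @useDynLib lipidfast
#' @importFrom stats setNames runif cor approx median pnorm quantile
#' @importFrom utils read.csv write.csv
NULL
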