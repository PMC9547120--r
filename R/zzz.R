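#' @importFrom stats setNames var rnorm runif pnorm pchisq dnorm optim optimHess complete.cases ave
#' @importFrom utils modifyList read.csv write.csv head
NULL

utils::globalVariables(".data")
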