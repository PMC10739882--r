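#' @keywords internal
"_PACKAGE"

#' @importFrom stats AIC coef cor fitted formula glm kruskal.test lm logLik
#'   mad median nobs p.adjust pchisq plogis pnorm qnorm quantile residuals
#'   rnorm runif sd setNames wilcox.test binomial as.formula complete.cases
#' @importFrom utils read.delim write.table
NULL

# Clamp a numeric vector to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Seconds -> milliseconds and back. All RT/error columns are in seconds,
# tolerance columns in milliseconds; every conversion goes through here.
s_to_ms <- function(x) x * 1000
ms_to_s <- function(x) x / 1000

stop_contract <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
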