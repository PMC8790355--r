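# Error-function helpers built on the normal CDF. erfcx uses the log tail of
# pnorm so that exp(shift - z^2) * erfcx(z) stays finite where erfc underflows.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# scaled complementary error function, exp(x^2) * erfc(x); x >= 0 assumed
erfcx <- function(x) {
  exp(x * x + log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE))
}

# exp(shift) * erfc(z), evaluated without overflow/underflow for z >= 0
exp_erfc <- function(shift, z) {
  out <- numeric(length(z))
  pos <- z >= 0
  if (any(pos)) {
    zp <- z[pos]
    out[pos] <- exp(shift[pos] - zp * zp) * erfcx(zp)
  }
  if (any(!pos)) out[!pos] <- exp(shift[!pos]) * erfc(z[!pos])
  out
}
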