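# One-off Gumbel fit for the +1/-1/-4/-1 local alignment scheme.
library(ighrep)
set.seed(1)
NT <- c("A","C","G","T")
m <- 350L; n <- 312L; N <- 2000L
ref <- paste(sample(NT, n, TRUE), collapse = "")
reads <- vapply(seq_len(N), function(i) paste(sample(NT, m, TRUE), collapse = ""), "")
s <- ighrep:::cpp_sw_score_batch(reads, ref, 1L, -1L, 4L, 1L)
# P(S >= x) = 1 - exp(-K m n exp(-lambda x)); tail regression on log(-log F)
xs <- sort(unique(s)); Fx <- ecdf(s)
x <- xs[Fx(xs) > 0.01 & Fx(xs) < 0.99]
y <- log(-log(Fx(x)))
fit <- lm(y ~ x)
lambda <- -coef(fit)[2]
K <- exp(coef(fit)[1]) / (m * n)
cat(sprintf("lambda = %.4f  K = %.4f\n", lambda, K))
cat("score range:", range(s), "\n")
# implied score threshold at E = 1e-3:
cat("S at E=1e-3:", log(K * m * n / 1e-3) / lambda, "\n")
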