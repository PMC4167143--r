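# Regenerates the PAM500 log-odds matrix shipped in R/pam.R.
#
# PAM-n scores are derived from the Dayhoff accepted-point-mutation model:
# a reversible rate matrix Q built from the Dayhoff exchangeabilities and
# stationary frequencies, scaled so one PAM unit equals 1% expected
# substitutions, exponentiated to n PAM, and converted to integer log-odds
# scores round(10 * log10(P_n(a,b) / f_b)).
#
# Sanity check: n = 250 reproduces the published PAM250 matrix (max abs
# deviation 1, from rounding).
#
# Usage: Rscript tools/make_pam500.R   (prints R source for the constant)

suppressMessages(library(phangorn))

aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

dayhoff <- get(".Dayhoff", environment(phangorn::pml))
bf <- as.numeric(dayhoff$bf)

R <- matrix(0, 20, 20, dimnames = list(aa, aa))
R[lower.tri(R)] <- dayhoff$Q
R <- R + t(R)

Q <- R * rep(bf, each = 20)  # Q[i, j] = R[i, j] * f_j
diag(Q) <- -rowSums(Q)
Q <- Q / (-sum(bf * diag(Q))) * 0.01  # 1 PAM = 1% expected substitutions

# reversible Q: exponentiate via the symmetrized eigen decomposition
Dh <- diag(sqrt(bf))
Dhi <- diag(1 / sqrt(bf))
S <- Dh %*% Q %*% Dhi
S <- (S + t(S)) / 2
ev <- eigen(S, symmetric = TRUE)

pam_scores <- function(n) {
  P <- Dhi %*% ev$vectors %*% diag(exp(ev$values * n)) %*% t(ev$vectors) %*% Dh
  sc <- round(10 * log10(sweep(P, 2, bf, "/")))
  sc <- (sc + t(sc)) / 2  # symmetrize any +/-1 rounding asymmetry
  storage.mode(sc) <- "integer"
  dimnames(sc) <- list(aa, aa)
  sc
}

p250 <- pam_scores(250)
ref <- {
  suppressMessages(library(Biostrings))
  data(PAM250, envir = environment())
  PAM250[aa, aa]
}
stopifnot(max(abs(p250 - ref)) <= 1)

p500 <- pam_scores(500)
cat("PAM500 <- matrix(c(\n")
cat(paste(apply(p500, 1, paste, collapse = "L, "), collapse = "L,\n"))
cat("L\n), nrow = 20, byrow = TRUE, dimnames = list(AA_STATES, AA_STATES))\n")
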