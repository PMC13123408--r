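# Independent oracles and programmatic fixtures shared by the tests.
# Everything here is deliberately written from first principles, not by
# calling the package's own implementation paths.

# Literal term-by-term transcription of the two PRE expressions, with its
# own copies of the constants. Inputs in SI (r in metres).
oracle_sbm <- function(S, ge, tau_c, gamma_I, B0, r_m) {
  mu0 <- 4 * pi * 1e-7
  muB <- 9.2740100783e-24
  hbar <- 1.054571817e-34
  wI <- gamma_I * B0
  we <- ge * muB * B0 / hbar
  JI <- tau_c / (1 + wI^2 * tau_c^2)
  Je <- tau_c / (1 + we^2 * tau_c^2)
  K <- (mu0 / (4 * pi))^2 * gamma_I^2 * ge^2 * muB^2 * S * (S + 1) / r_m^6
  list(gamma1 = (2 / 15) * K * (3 * JI + 7 * Je),
       gamma2 = (1 / 15) * K * (4 * tau_c + 3 * JI + 13 * Je))
}

# frozen values computed with an independent Python transcription
ORACLE <- list(
  gamma1_ref = 122.3570757248,    # S=7/2 ge=2.00232 tau_c=100ps 19F 14.09T r=10A
  gamma2_ref = 153.0171185630,
  J_600MHz_100ps = 8.755629734612e-11,
  dip_HH_2A = 15015.02014358,     # Hz
  dip_HF_2A = 14133.43444010,     # Hz
  snr_argmax = 1.256431
)

# brute-force grid-search minimizer for the two-parameter mono-exponential
# models, used as an oracle for the least-squares fits
grid_fit_monoexp <- function(delays, y, type, amp_range, rate_range,
                             n = 201) {
  amps <- seq(amp_range[1], amp_range[2], length.out = n)
  rates <- seq(rate_range[1], rate_range[2], length.out = n)
  best <- c(NA, NA, Inf)
  for (a in amps) {
    model <- if (type == "recovery") {
      outer(delays, rates, function(t, r) a * (1 - exp(-t * r)))
    } else {
      outer(delays, rates, function(t, r) a * exp(-t * r))
    }
    sse <- colSums((model - y)^2)
    k <- which.min(sse)
    if (sse[k] < best[3]) best <- c(a, rates[k], sse[k])
  }
  list(amplitude = best[1], rate = best[2], sse = best[3],
       amp_step = diff(amp_range) / (n - 1),
       rate_step = diff(rate_range) / (n - 1))
}

# minimal PDB writer for programmatic fixtures
pdb_line <- function(i, atom, res, ch, rn, x, y, z, el) {
  sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    i, atom, res, ch, rn, x, y, z, el)
}

write_toy_pdb <- function(rows, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    pdb_line(i, r$atom, r$res, r$ch, r$rn, r$x, r$y, r$z, r$el)
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

pdb_row <- function(atom, res, ch, rn, x, y, z, el) {
  data.frame(atom = atom, res = res, ch = ch, rn = rn, x = x, y = y, z = z,
             el = el, stringsAsFactors = FALSE)
}

# a single tryptophan side chain with realistic indole geometry (flat ring,
# bond lengths ~1.4 A), enough for CZ3-based descriptor work
toy_trp <- function(ch = "A", rn = 1, offset = c(0, 0, 0)) {
  at <- rbind(
    pdb_row("N",   "TRP", ch, rn, 0.0, 0.0, 0.0, "N"),
    pdb_row("CA",  "TRP", ch, rn, 1.45, 0.0, 0.0, "C"),
    pdb_row("C",   "TRP", ch, rn, 2.1, 1.3, 0.0, "C"),
    pdb_row("O",   "TRP", ch, rn, 1.5, 2.4, 0.0, "O"),
    pdb_row("CB",  "TRP", ch, rn, 2.2, -1.2, 0.5, "C"),
    pdb_row("CG",  "TRP", ch, rn, 3.6, -1.3, 0.2, "C"),
    pdb_row("CD1", "TRP", ch, rn, 4.3, -2.4, 0.2, "C"),
    pdb_row("NE1", "TRP", ch, rn, 5.6, -2.2, 0.0, "N"),
    pdb_row("CE2", "TRP", ch, rn, 5.8, -0.9, 0.0, "C"),
    pdb_row("CD2", "TRP", ch, rn, 4.6, -0.3, 0.1, "C"),
    pdb_row("CE3", "TRP", ch, rn, 4.5, 1.1, 0.1, "C"),
    pdb_row("CZ3", "TRP", ch, rn, 5.7, 1.8, 0.0, "C"),
    pdb_row("CH2", "TRP", ch, rn, 6.9, 1.1, -0.1, "C"),
    pdb_row("CZ2", "TRP", ch, rn, 7.0, -0.2, -0.1, "C")
  )
  at$x <- at$x + offset[1]; at$y <- at$y + offset[2]
  at$z <- at$z + offset[3]
  at
}
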