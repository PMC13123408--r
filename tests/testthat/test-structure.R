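test_that("PDB parsing returns exact coordinates and bookkeeping", {
  rows <- rbind(pdb_row("N", "GLY", "A", 1, 0.1, 0.2, 0.3, "N"),
                pdb_row("CA", "GLY", "A", 1, 1.55, 0.2, 0.3, "C"),
                pdb_row("C", "GLY", "A", 1, 2.1, 1.6, 0.3, "C"))
  m <- read_pdb(write_toy_pdb(rows))
  expect_equal(nrow(m), 3)
  expect_equal(m$x, c(0.1, 1.55, 2.1))
  expect_equal(m$element, c("N", "C", "C"))
  trp <- read_pdb(write_toy_pdb(toy_trp()))
  expect_true("CZ3" %in% trp$atom)
  expect_error(read_pdb(tempfile(fileext = ".pdb")), "failed to parse")
})

test_that("explicit hydrogens are filtered by their bonded heavy atom", {
  rows <- rbind(pdb_row("N", "GLY", "A", 2, 0, 0, 0, "N"),
                pdb_row("H", "GLY", "A", 2, -0.95, 0.3, 0, "H"),
                pdb_row("CA", "GLY", "A", 2, 1.45, 0, 0, "C"),
                pdb_row("HA2", "GLY", "A", 2, 1.8, -1.0, 0, "H"),
                pdb_row("C", "GLY", "A", 2, 2.1, 1.35, 0, "C"),
                pdb_row("O", "GLY", "A", 2, 1.5, 2.4, 0, "O"))
  pr <- select_exchangeable_protons(read_pdb(write_toy_pdb(rows)))
  expect_equal(nrow(pr), 1)           # amide H only, HA excluded
  expect_equal(pr$site, "H")
  expect_equal(pr$n_H, 1)
})

test_that("constructed amide protons satisfy the trans geometry", {
  rows <- rbind(pdb_row("N", "GLY", "A", 1, 0, 0, 0, "N"),
                pdb_row("CA", "GLY", "A", 1, 1.45, 0, 0, "C"),
                pdb_row("C", "GLY", "A", 1, 2.0, 1.4, 0, "C"),
                pdb_row("O", "GLY", "A", 1, 1.3, 2.4, 0, "O"),
                pdb_row("N", "ALA", "A", 2, 3.33, 1.45, 0, "N"),
                pdb_row("CA", "ALA", "A", 2, 4.1, 2.7, 0, "C"),
                pdb_row("C", "ALA", "A", 2, 5.6, 2.5, 0, "C"),
                pdb_row("O", "ALA", "A", 2, 6.2, 1.45, 0, "O"))
  pr <- select_exchangeable_protons(read_pdb(write_toy_pdb(rows)))
  expect_equal(nrow(pr), 1)            # residue 2 amide; residue 1 is N-term
  N <- c(3.33, 1.45, 0); CA <- c(4.1, 2.7, 0); Cp <- c(2.0, 1.4, 0)
  H <- c(pr$x, pr$y, pr$z)
  # analytic geometry: 1.01 A bond, in the N/CA/C(i-1) plane, bisecting
  # the CA-N-C(i-1) angle on the far (trans) side
  expect_equal(sqrt(sum((H - N)^2)), 1.01, tolerance = 1e-9)
  expect_equal(H[3], 0, tolerance = 1e-9)
  u <- (H - N) / sqrt(sum((H - N)^2))
  a <- (CA - N) / sqrt(sum((CA - N)^2))
  b <- (Cp - N) / sqrt(sum((Cp - N)^2))
  expect_equal(sum(u * a), sum(u * b), tolerance = 1e-9)  # bisector
  expect_lt(sum(u * a), 0)                                # points away
})

test_that("dipolar couplings match the frozen oracle and scale as r^-3", {
  gH <- gyromagnetic_ratio("1H"); gF <- gyromagnetic_ratio("19F")
  expect_equal(dipolar_coupling(gH, gH, 2), ORACLE$dip_HH_2A,
               tolerance = 1e-10)
  expect_equal(dipolar_coupling(gH, gF, 2), ORACLE$dip_HF_2A,
               tolerance = 1e-10)
  expect_equal(dipolar_coupling(gH, gH, 4), ORACLE$dip_HH_2A / 8,
               tolerance = 1e-12)
  expect_equal(dipolar_coupling(gH, gF, 3) / dipolar_coupling(gH, gH, 3),
               gF / gH, tolerance = 1e-12)
  expect_error(dipolar_coupling(gH, gH, -1), "r must be")
})

test_that("d_rss matches a brute-force pairwise oracle", {
  m <- read_pdb(write_toy_pdb(toy_trp()))
  cz3 <- as.numeric(m[m$atom == "CZ3", c("x", "y", "z")])
  # one proton at 5 A
  p1 <- data.frame(x = cz3[1] + 5, y = cz3[2], z = cz3[3], n_H = 1)
  d1 <- d_rss(m, 1, protons = p1)
  expect_equal(d1$d_rss_Hz,
               dipolar_coupling(gyromagnetic_ratio("19F"),
                                gyromagnetic_ratio("1H"), 5),
               tolerance = 1e-12)
  # two protons at equal distance: sqrt(2) times one
  p2 <- rbind(p1, data.frame(x = cz3[1] - 5, y = cz3[2], z = cz3[3],
                             n_H = 1))
  expect_equal(d_rss(m, 1, protons = p2)$d_rss_Hz, sqrt(2) * d1$d_rss_Hz,
               tolerance = 1e-12)
  # 50 random protons against an independent double-loop transcription
  set.seed(17)
  p50 <- data.frame(x = cz3[1] + runif(50, -20, 20),
                    y = cz3[2] + runif(50, -20, 20),
                    z = cz3[3] + runif(50, -20, 20), n_H = 1)
  mu0 <- 4 * pi * 1e-7; hbar <- 1.054571817e-34
  gH <- 2.6752218744e8; gF <- 2.51815e8
  acc <- 0
  for (i in 1:50) {
    r <- sqrt(sum((c(p50$x[i], p50$y[i], p50$z[i]) - cz3)^2)) * 1e-10
    acc <- acc + ((mu0 / (4 * pi)) * gF * gH * hbar / (2 * pi * r^3))^2
  }
  expect_equal(d_rss(m, 1, protons = p50)$d_rss_Hz, sqrt(acc),
               tolerance = 1e-12)
  # alpha^-3 scaling under uniform coordinate dilation
  alpha <- 1.7
  ms <- m; ms$x <- alpha * m$x; ms$y <- alpha * m$y; ms$z <- alpha * m$z
  ps <- p50; ps$x <- alpha * p50$x; ps$y <- alpha * p50$y
  ps$z <- alpha * p50$z
  expect_equal(d_rss(ms, 1, protons = ps)$d_rss_Hz,
               d_rss(m, 1, protons = p50)$d_rss_Hz / alpha^3,
               tolerance = 1e-10)
  expect_error(d_rss(m, 99), "no CZ3|has no")
})

test_that("SASA reproduces analytic spheres and buried atoms", {
  lone <- read_pdb(write_toy_pdb(pdb_row("CA", "GLY", "A", 1, 0, 0, 0, "C")))
  expect_equal(sasa(lone), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # an atom caged tightly by large neighbours has zero accessible area
  cage <- expand.grid(x = c(-1.2, 1.2), y = c(-1.2, 1.2), z = c(-1.2, 1.2))
  rows <- pdb_row("C1", "LIG", "A", 1, 0, 0, 0, "C")
  for (i in seq_len(nrow(cage))) {
    rows <- rbind(rows, pdb_row(paste0("S", i), "LIG", "A", 2,
                                cage$x[i], cage$y[i], cage$z[i], "S"))
  }
  m <- read_pdb(write_toy_pdb(rows))
  per_atom <- sasa(m)
  expect_equal(per_atom[1], 0)
  expect_true(all(per_atom >= 0))
  # assembly SASA never exceeds the sum of isolated-atom SASAs
  iso <- 4 * pi * (c(1.7, rep(1.8, 8)) + 1.4)^2
  expect_lt(sum(per_atom), sum(iso))
})

test_that("two partially overlapping atoms match the spherical-cap formula", {
  d <- 2.5
  m <- read_pdb(write_toy_pdb(rbind(
    pdb_row("C1", "LIG", "A", 1, 0, 0, 0, "C"),
    pdb_row("O1", "LIG", "A", 1, d, 0, 0, "O"))))
  per_atom <- sasa(m)
  R1 <- 1.7 + 1.4; R2 <- 1.52 + 1.4
  # exact buried cap on sphere 1: points within R2 of the second centre
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  expect_equal(per_atom[1], 4 * pi * R1^2 - 2 * pi * R1 * h1,
               tolerance = 0.02)
  expect_equal(per_atom[2], 4 * pi * R2^2 - 2 * pi * R2 * h2,
               tolerance = 0.02)
  expect_error(sasa(read_pdb(write_toy_pdb(
    pdb_row("X", "LIG", "A", 1, 0, 0, 0, "XX")))), "radius")
})

test_that("per-tryptophan descriptors assemble across chains", {
  rows <- rbind(toy_trp("A", 1), toy_trp("B", 1, offset = c(20, 0, 0)))
  m <- read_pdb(write_toy_pdb(rows))
  d <- structure_descriptors(m)
  expect_equal(nrow(d), 2)
  expect_setequal(d$label, c("A/W1", "B/W1"))
  expect_true(all(d$d_rss_Hz >= 0))
  expect_true(all(d$sasa_A2 >= 0))
  # assembly context: both chains' NE1 protons contribute to each d_rss
  d_mono <- structure_descriptors(m, monomer = TRUE)
  expect_true(all(d$d_rss_Hz >= d_mono$d_rss_Hz))
})

test_that("descriptor correlations use the exact permutation null", {
  x <- c(1, 2.5, 3, 5)
  expect_equal(correlate_descriptors(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_descriptors(x, -3 * x)$r, -1)
  g <- c(0.2, 0.9, 0.4, 0.7)
  res <- correlate_descriptors(x, g)
  # independent enumeration of all 24 label permutations by nested loops
  perms <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j))) {
    perms[[length(perms) + 1]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
  }
  r_obs <- cor(x, g)
  r_all <- vapply(perms, function(p) cor(x, g[p]), 0)
  expect_equal(res$p_perm, mean(abs(r_all) >= abs(r_obs) - 1e-12))
  expect_true(res$p_perm >= 1 / 24 && res$p_perm <= 1)
  expect_error(correlate_descriptors(x[1:2], g[1:2]), ">= 3")
})
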