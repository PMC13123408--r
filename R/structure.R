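# Structure-based descriptors for rationalising per-residue PREs:
# the root-sum-square dipolar coupling between the fluorine site of each
# tryptophan and the back-exchangeable protons of the assembly (a proxy
# for the spin-diffusion network), and the solvent-accessible surface area
# of each tryptophan (a proxy for the dopant's distance of closest
# approach).

#' Read a protein structure from a PDB file
#'
#' Thin wrapper around `bio3d::read.pdb` returning a plain atom table.
#'
#' @param path Path to a PDB file.
#' @return Object of class `structure_model`: a data.frame with columns
#'   `element`, `atom`, `resid`, `resno`, `chain`, `x`, `y`, `z`
#'   (coordinates in angstrom), with the source path as attribute.
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  at <- pdb$atom
  element <- trimws(at$elesy)
  fallback <- !nzchar(element) | is.na(element)
  if (any(fallback)) {
    # derive from the atom name: strip digits, take the leading letter(s)
    nm <- gsub("[0-9']", "", at$elety[fallback])
    element[fallback] <- ifelse(substr(nm, 1, 1) %in%
                                  c("H", "C", "N", "O", "S", "P", "F"),
                                substr(nm, 1, 1), substr(nm, 1, 2))
  }
  m <- data.frame(element = element, atom = trimws(at$elety),
                  resid = trimws(at$resid), resno = at$resno,
                  chain = ifelse(is.na(at$chain), "A", at$chain),
                  x = at$x, y = at$y, z = at$z,
                  stringsAsFactors = FALSE)
  if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  attr(m, "source") <- path
  class(m) <- c("structure_model", "data.frame")
  m
}

# side-chain heavy atoms that carry exchangeable protons, with proton counts
.exchangeable_sites <- list(
  SER = c(OG = 1), THR = c(OG1 = 1), TYR = c(OH = 1), CYS = c(SG = 1),
  LYS = c(NZ = 3), ARG = c(NE = 1, NH1 = 2, NH2 = 2),
  ASN = c(ND2 = 2), GLN = c(NE2 = 2), HIS = c(ND1 = 1, NE2 = 1),
  TRP = c(NE1 = 1)
)

.unit <- function(v) v / sqrt(sum(v^2))

#' Select back-exchangeable protons
#'
#' Back-exchangeable protons are the backbone amide hydrogens plus
#' hydrogens bound to side-chain N, O or S — the set that is re-protonated
#' when a perdeuterated protein is exchanged back into H2O buffer.
#'
#' If the model contains explicit hydrogens, a hydrogen is kept when its
#' nearest heavy atom within 1.3 angstrom is N, O or S (aliphatic and
#' aromatic C-H are excluded). If the model has no hydrogens, amide protons
#' are constructed geometrically (1.01 angstrom from N, trans to the
#' preceding carbonyl, i.e. along the negated bisector of the N-CA and
#' N-C(i-1) directions) and side-chain exchangeable protons are placed
#' 1.0 angstrom from their heavy atom, pointing away from its bonded
#' neighbours, carrying the standard proton count of the site as a weight.
#'
#' @param model A [read_pdb()] result (or compatible data.frame).
#' @param chain Optional chain filter; default all chains.
#' @return data.frame with columns `x`, `y`, `z`, `n_H` (proton
#'   multiplicity at that position), `resno`, `chain`, `site`.
#' @export
select_exchangeable_protons <- function(model, chain = NULL) {
  if (nrow(model) == 0) stop("empty structure model", call. = FALSE)
  m <- if (is.null(chain)) model else model[model$chain %in% chain, ]
  if (nrow(m) == 0) stop("no atoms in requested chain(s)", call. = FALSE)
  hyd <- m$element == "H"
  if (any(hyd)) {
    heavy <- m[!hyd, ]
    hxyz <- as.matrix(m[hyd, c("x", "y", "z")])
    keep <- logical(nrow(hxyz))
    donor_elem <- character(nrow(hxyz))
    hv <- as.matrix(heavy[, c("x", "y", "z")])
    for (i in seq_len(nrow(hxyz))) {
      d2 <- colSums((t(hv) - hxyz[i, ])^2)
      j <- which.min(d2)
      if (d2[j] <= 1.3^2) {
        donor_elem[i] <- heavy$element[j]
        keep[i] <- heavy$element[j] %in% c("N", "O", "S")
      }
    }
    hm <- m[hyd, ][keep, ]
    return(data.frame(x = hm$x, y = hm$y, z = hm$z, n_H = 1,
                      resno = hm$resno, chain = hm$chain, site = hm$atom,
                      stringsAsFactors = FALSE))
  }
  # no explicit hydrogens: construct them
  out <- list()
  for (ch in unique(m$chain)) {
    mc <- m[m$chain == ch, ]
    resnos <- sort(unique(mc$resno))
    for (k in seq_along(resnos)) {
      rn <- resnos[k]
      res <- mc[mc$resno == rn, ]
      resname <- res$resid[1]
      get <- function(a, df = res) {
        r <- df[df$atom == a, c("x", "y", "z")]
        if (nrow(r) == 1) as.numeric(r) else NULL
      }
      # backbone amide H: needs N, CA here and C of the preceding residue
      if (k > 1 && resname != "PRO") {
        prev <- mc[mc$resno == resnos[k - 1], ]
        N <- get("N"); CA <- get("CA"); Cp <- get("C", prev)
        if (!is.null(N) && !is.null(CA) && !is.null(Cp) &&
            resnos[k - 1] == rn - 1) {
          dir <- -.unit(.unit(CA - N) + .unit(Cp - N))
          H <- N + 1.01 * dir
          out[[length(out) + 1]] <- data.frame(
            x = H[1], y = H[2], z = H[3], n_H = 1, resno = rn, chain = ch,
            site = "H", stringsAsFactors = FALSE)
        }
      }
      sites <- .exchangeable_sites[[resname]]
      if (!is.null(sites)) {
        for (a in names(sites)) {
          X <- get(a)
          if (is.null(X)) next
          nb <- as.matrix(res[res$atom != a, c("x", "y", "z")])
          d <- sqrt(colSums((t(nb) - X)^2))
          bonded <- nb[d < 1.8, , drop = FALSE]
          dir <- if (nrow(bonded) > 0) {
            .unit(X - colMeans(bonded))
          } else {
            .unit(X - colMeans(as.matrix(res[, c("x", "y", "z")])))
          }
          H <- X + 1.0 * dir
          out[[length(out) + 1]] <- data.frame(
            x = H[1], y = H[2], z = H[3], n_H = unname(sites[[a]]),
            resno = rn, chain = ch, site = paste0("H@", a),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    stop("no exchangeable protons found or constructible", call. = FALSE)
  }
  do.call(rbind, out)
}

#' Dipolar coupling constant between two nuclei
#'
#' Magnitude of the through-space dipolar coupling
#' `(mu0/4pi) * gamma_a * gamma_b * hbar / (2 pi r^3)` in Hz.
#'
#' @param gamma_a,gamma_b Gyromagnetic ratios in rad s^-1 T^-1 (see
#'   [gyromagnetic_ratio()]).
#' @param r Internuclear distance in angstrom, `> 0`. Vectorised.
#' @return Coupling in Hz.
#' @export
dipolar_coupling <- function(gamma_a, gamma_b, r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be > 0", call. = FALSE)
  cst <- .pre_const
  (cst$mu0 / (4 * pi)) * gamma_a * gamma_b * cst$hbar /
    (2 * pi * (r * 1e-10)^3)
}

#' Root-sum-square dipolar coupling of a tryptophan fluorine site
#'
#' `sqrt(sum_j n_j d(F, H_j)^2)` over the back-exchangeable proton set,
#' with the fluorine position approximated by the residue's CZ3 atom (the
#' 5-position of the indole ring, the fluorination site). By default the
#' proton set spans the full model (all chains of the assembly).
#'
#' @param model A [read_pdb()] result.
#' @param resno Residue number of the tryptophan.
#' @param chain Chain of the tryptophan (default first chain containing
#'   `resno`).
#' @param proxy_atom Atom used as the fluorine position (default `"CZ3"`).
#' @param protons Optional precomputed proton set from
#'   [select_exchangeable_protons()]; computed over all chains if missing.
#' @param monomer If TRUE, restrict the proton set to the residue's chain.
#' @return List with `d_rss_Hz`, `n_protons_used` (sum of multiplicities)
#'   and the proxy position.
#' @export
d_rss <- function(model, resno, chain = NULL, proxy_atom = "CZ3",
                  protons = NULL, monomer = FALSE) {
  sel <- model$resno == resno & model$atom == proxy_atom
  if (!is.null(chain)) sel <- sel & model$chain == chain
  hit <- model[sel, ]
  if (nrow(hit) == 0) {
    stop("residue ", resno, " has no ", proxy_atom, " atom", call. = FALSE)
  }
  hit <- hit[1, ]
  if (is.null(protons)) {
    protons <- select_exchangeable_protons(
      model, chain = if (monomer) hit$chain else NULL)
  }
  Fpos <- c(hit$x, hit$y, hit$z)
  r <- sqrt((protons$x - Fpos[1])^2 + (protons$y - Fpos[2])^2 +
            (protons$z - Fpos[3])^2)
  ok <- r > 1e-6
  d <- dipolar_coupling(gyromagnetic_ratio("19F"),
                        gyromagnetic_ratio("1H"), r[ok])
  list(d_rss_Hz = sqrt(sum(protons$n_H[ok] * d^2)),
       n_protons_used = sum(protons$n_H[ok]),
       proxy_xyz = Fpos)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.vdw_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, F = 1.47,
                P = 1.8)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe SASA: each atom is inflated by the probe radius, sampled
#' with a deterministic quasi-uniform point set, and the accessible
#' fraction is the share of points not buried inside any neighbouring
#' inflated sphere. Computed in the context of the full model.
#'
#' @param model A [read_pdb()] result.
#' @param resno Optional residue number: return the summed SASA of that
#'   residue's atoms (with `chain` to disambiguate). If NULL, per-atom
#'   SASAs for the whole model are returned.
#' @param chain Optional chain filter for the reported residue.
#' @param probe Probe radius in angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Named van-der-Waals radii in angstrom by element.
#' @return If `resno` is given, the residue SASA in squared angstrom;
#'   otherwise a numeric vector of per-atom SASAs.
#' @export
sasa <- function(model, resno = NULL, chain = NULL, probe = 1.4,
                 n_points = 960, radii = .vdw_radii) {
  unknown <- setdiff(unique(model$element), names(radii))
  if (length(unknown) > 0) {
    stop("no van-der-Waals radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  R <- unname(radii[model$element]) + probe
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  out <- numeric(n)
  # target atoms: all, or just the requested residue (neighbours still count)
  targets <- seq_len(n)
  if (!is.null(resno)) {
    t_sel <- model$resno == resno
    if (!is.null(chain)) t_sel <- t_sel & model$chain == chain
    if (!any(t_sel)) stop("residue not found", call. = FALSE)
    targets <- which(t_sel)
  }
  for (i in targets) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (R[i] + R)^2 & d2 > 1e-12)
    surf <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  if (!is.null(resno)) sum(out[targets]) else out
}

#' Per-tryptophan structure descriptors
#'
#' Computes d_rss and SASA for every tryptophan (by default in every
#' chain) of a structure.
#'
#' @param model A [read_pdb()] result.
#' @param proxy_atom Fluorine proxy atom (default `"CZ3"`).
#' @param chains Optional chain subset for the reported tryptophans (the
#'   descriptor context is always the full model).
#' @param monomer If TRUE, d_rss uses only the residue's own chain.
#' @return data.frame: chain, resno, label (e.g. `"A/W164"`), d_rss_Hz,
#'   sasa_A2, n_protons_used.
#' @export
structure_descriptors <- function(model, proxy_atom = "CZ3", chains = NULL,
                                  monomer = FALSE) {
  trp <- unique(model[model$resid == "TRP" & model$atom == proxy_atom,
                      c("chain", "resno")])
  if (!is.null(chains)) trp <- trp[trp$chain %in% chains, ]
  if (nrow(trp) == 0) {
    stop("no tryptophan with a ", proxy_atom, " atom found", call. = FALSE)
  }
  protons <- if (monomer) NULL else select_exchangeable_protons(model)
  rows <- lapply(seq_len(nrow(trp)), function(i) {
    ch <- trp$chain[i]; rn <- trp$resno[i]
    dr <- d_rss(model, rn, chain = ch, proxy_atom = proxy_atom,
                protons = protons, monomer = monomer)
    data.frame(chain = ch, resno = rn, label = paste0(ch, "/W", rn),
               d_rss_Hz = dr$d_rss_Hz,
               sasa_A2 = sasa(model, resno = rn, chain = ch),
               n_protons_used = dr$n_protons_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# all permutations of 1..n (n <= 7)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Correlate structure descriptors with measured PREs
#'
#' Pearson correlation with an exact two-sided permutation p-value (all
#' `n!` label permutations enumerated for `n <= 7`): the p-value is the
#' fraction of permutations whose |r| is at least the observed |r|.
#'
#' @param descriptor Numeric descriptor values (e.g. d_rss or SASA),
#'   `>= 3` points.
#' @param gamma Measured PRE slopes, same residues and order.
#' @return List with `r` (Pearson), `p_perm` and `n`.
#' @export
correlate_descriptors <- function(descriptor, gamma) {
  n <- length(descriptor)
  if (n < 3 || length(gamma) != n) {
    stop("need >= 3 paired (descriptor, Gamma) values", call. = FALSE)
  }
  if (n > 7) stop("exact enumeration limited to n <= 7", call. = FALSE)
  r_obs <- stats::cor(descriptor, gamma)
  perms <- .permutations(n)
  r_perm <- apply(perms, 1, function(p) stats::cor(descriptor, gamma[p]))
  list(r = r_obs,
       p_perm = mean(abs(r_perm) >= abs(r_obs) - 1e-12),
       n = n)
}
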