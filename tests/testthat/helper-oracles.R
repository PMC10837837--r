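# Independent oracles used by the tests. These deliberately re-derive results
# with the most literal possible implementations (explicit loops, closed
# forms) and share no code with the package internals they check.

# brute-force N50: walk prefixes of the descending-sorted lengths
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# brute-force all-pairs interaction scan with explicit group definitions
oracle_contacts <- function(atoms, th = interaction_thresholds()) {
  eps <- 1e-9
  res <- unique(atoms$residue_index)
  typ <- vapply(res, function(r) atoms$residue_type[atoms$residue_index == r][1],
                character(1))
  coords <- function(r, names_wanted) {
    sel <- atoms$residue_index == r & atoms$atom_name %in% names_wanted
    if (sum(sel) < length(names_wanted)) return(NULL)
    as.matrix(atoms[sel, c("x", "y", "z")])
  }
  cent <- function(m) if (is.null(m)) NULL else colMeans(m)
  rings <- list(PHE = c("CG","CD1","CD2","CE1","CE2","CZ"),
                TYR = c("CG","CD1","CD2","CE1","CE2","CZ"),
                TRP = c("CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
                HIS = c("CG","ND1","CD2","CE1","NE2"))
  cations <- list(ARG = c("NH1","NH2","NE"), LYS = "NZ", HIS = c("ND1","NE2"))
  anions <- list(ASP = c("OD1","OD2"), GLU = c("OE1","OE2"))
  hydroph <- c("ALA","VAL","LEU","ILE","MET","PHE","TRP","PRO","TYR")
  cpi <- c(LYS = "NZ", ARG = "CZ")
  sulf <- c(CYS = "SG", MET = "SD")
  out <- list()
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  for (ii in seq_along(res)) for (jj in seq_along(res)) {
    if (jj <= ii) next
    i <- res[ii]; j <- res[jj]
    ti <- typ[ii]; tj <- typ[jj]
    if (ti == "CYS" && tj == "CYS") {
      si <- cent(coords(i, "SG")); sj <- cent(coords(j, "SG"))
      if (!is.null(si) && !is.null(sj)) {
        d <- dist3(si, sj)
        if (d <= th$disulfide + eps) {
          out[[length(out) + 1]] <- data.frame(type = "disulfide", res_i = i,
                                               res_j = j, distance = d)
        }
      }
    }
    if (abs(j - i) < 2) next
    if (ti %in% hydroph && tj %in% hydroph) {
      ci <- atoms[atoms$residue_index == i & atoms$element == "C" &
                    !(atoms$atom_name %in% c("CA", "C")), c("x","y","z")]
      cj <- atoms[atoms$residue_index == j & atoms$element == "C" &
                    !(atoms$atom_name %in% c("CA", "C")), c("x","y","z")]
      if (nrow(ci) > 0 && nrow(cj) > 0) {
        best <- Inf
        for (a in seq_len(nrow(ci))) for (b in seq_len(nrow(cj))) {
          best <- min(best, dist3(as.numeric(ci[a, ]), as.numeric(cj[b, ])))
        }
        if (best <= th$hydrophobic + eps) {
          out[[length(out) + 1]] <- data.frame(type = "hydrophobic", res_i = i,
                                               res_j = j, distance = best)
        }
      }
    }
    ds <- c()
    if (ti %in% names(cations) && tj %in% names(anions)) {
      a <- cent(coords(i, cations[[ti]])); b <- cent(coords(j, anions[[tj]]))
      if (!is.null(a) && !is.null(b)) ds <- c(ds, dist3(a, b))
    }
    if (ti %in% names(anions) && tj %in% names(cations)) {
      a <- cent(coords(i, anions[[ti]])); b <- cent(coords(j, cations[[tj]]))
      if (!is.null(a) && !is.null(b)) ds <- c(ds, dist3(a, b))
    }
    if (length(ds) > 0 && min(ds) <= th$ionic + eps) {
      out[[length(out) + 1]] <- data.frame(type = "ionic", res_i = i, res_j = j,
                                           distance = min(ds))
    }
    ri <- if (ti %in% names(rings)) cent(coords(i, rings[[ti]])) else NULL
    rj <- if (tj %in% names(rings)) cent(coords(j, rings[[tj]])) else NULL
    if (!is.null(ri) && !is.null(rj)) {
      d <- dist3(ri, rj)
      if (d >= th$aromatic_min - eps && d <= th$aromatic_max + eps) {
        out[[length(out) + 1]] <- data.frame(type = "aromatic_aromatic",
                                             res_i = i, res_j = j, distance = d)
      }
    }
    ds <- c()
    if (ti %in% names(sulf) && !is.null(rj)) {
      a <- cent(coords(i, sulf[[ti]]))
      if (!is.null(a)) ds <- c(ds, dist3(a, rj))
    }
    if (tj %in% names(sulf) && !is.null(ri)) {
      a <- cent(coords(j, sulf[[tj]]))
      if (!is.null(a)) ds <- c(ds, dist3(a, ri))
    }
    if (length(ds) > 0 && min(ds) <= th$aromatic_sulfur + eps) {
      out[[length(out) + 1]] <- data.frame(type = "aromatic_sulfur", res_i = i,
                                           res_j = j, distance = min(ds))
    }
    ds <- c()
    if (ti %in% names(cpi) && !is.null(rj)) {
      a <- cent(coords(i, cpi[[ti]]))
      if (!is.null(a)) ds <- c(ds, dist3(a, rj))
    }
    if (tj %in% names(cpi) && !is.null(ri)) {
      a <- cent(coords(j, cpi[[tj]]))
      if (!is.null(a)) ds <- c(ds, dist3(a, ri))
    }
    if (length(ds) > 0 && min(ds) <= th$cation_pi + eps) {
      out[[length(out) + 1]] <- data.frame(type = "cation_pi", res_i = i,
                                           res_j = j, distance = min(ds))
    }
  }
  if (length(out) == 0) {
    return(data.frame(type = character(), res_i = integer(), res_j = integer(),
                      distance = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$type, df$res_i, df$res_j), ]
}

# Monte-Carlo SASA of atom i in a cluster: uniform random points on the
# expanded sphere, rejected if inside any other expanded sphere
oracle_mc_sasa <- function(atoms, i, n_samples = 1e5,
                           radii = vdw_radii(), probe = 1.4) {
  lut <- setNames(radii$radius, radii$element)
  rexp <- unname(lut[atoms$element]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  z <- 2 * runif(n_samples) - 1
  th <- runif(n_samples, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  p <- sweep(cbind(r * cos(th), r * sin(th), z) * rexp[i], 2, xyz[i, ], "+")
  exposed <- rep(TRUE, n_samples)
  for (j in setdiff(seq_len(nrow(atoms)), i)) {
    dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
    exposed <- exposed & (dd >= rexp[j]^2)
  }
  4 * pi * rexp[i]^2 * mean(exposed)
}

# independent Henderson-Hasselbalch pI via uniroot on the net charge
oracle_pi <- function(sequence, pka = pka_set()) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  pk <- setNames(pka$pka, pka$group)
  sign_of <- setNames(ifelse(pka$charge == "positive", 1, -1), pka$group)
  q <- function(ph) {
    total <- sign_of["Nterm"] / (1 + 10^(ph - pk["Nterm"])) -
      1 / (1 + 10^(pk["Cterm"] - ph))
    for (g in c("K", "R", "H")) {
      total <- total + sum(ch == g) / (1 + 10^(ph - pk[g]))
    }
    for (g in c("D", "E", "C", "Y")) {
      total <- total - sum(ch == g) / (1 + 10^(pk[g] - ph))
    }
    unname(total)
  }
  uniroot(q, c(0, 14), tol = 1e-10)$root
}

# random protein sequence over the 20 standard letters
random_protein <- function(n, letters = c("A","R","N","D","C","Q","E","G","H",
                                          "I","L","K","M","F","P","S","T","W",
                                          "Y","V")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# a random "structure" of template residues scattered in a box: each residue
# is the side chain of a singleton peptide translated to a random position
random_residue_cluster <- function(n_res, box = 18,
                                   types = c("ALA","LEU","PHE","TYR","TRP",
                                             "HIS","ARG","LYS","ASP","GLU",
                                             "CYS","MET","VAL","SER")) {
  pieces <- lapply(seq_len(n_res), function(i) {
    ty <- sample(types, 1)
    at <- build_peptide(ty, "extended")
    shift <- runif(3, 0, box)
    at$residue_index <- i
    at$x <- at$x + shift[1]; at$y <- at$y + shift[2]; at$z <- at$z + shift[3]
    at
  })
  do.call(rbind, pieces)
}

# a scaled-down genome-generator configuration used across tests: feature
# counts shrunk with the genome so the planted features always pack
small_sim_config <- function(n_isolates = 2) {
  cl <- genome_sim_config()$clades
  cl$mean_srna <- c(8, 14, 8, 8)
  cl$mean_is <- c(3, 6, 6, 6)
  cl$mean_operon <- c(5, 8, 8, 8)
  genome_sim_config(n_isolates = n_isolates, genome_length = 40000,
                    clades = cl, n_cds = 25, cds_codon_range = c(80, 160),
                    n_rrna = 2, n_promoters = 15)
}
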