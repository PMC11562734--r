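# Low-level molecule handling on top of OpenBabel (via ChemmineOB).
#
# A "mol" is a plain list describing one molecule (possibly multi-component):
#   atoms  : tibble(element, charge, degree, in_ring)
#   bonds  : tibble(a1, a2, order)   (1-based atom indices, a1 < a2)
#   n_atoms, n_bonds, net_charge, smiles (canonical)
# Only heavy atoms are represented; hydrogens stay implicit, as in the
# V2000 connection table OpenBabel emits.

ob_convert <- function(from, to, source) {
  ChemmineOB::convertFormat(from, to, source)
}

# SDF charge-column codes (V2000 field 6) -> formal charge.
.sdf_charge_code <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)

parse_molblock <- function(block) {
  lines <- block
  if (length(lines) < 4L) stop_parse("Truncated molblock.")
  counts <- lines[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || is.na(n_bonds)) stop_parse("Malformed V2000 counts line.")
  atom_lines <- lines[seq_len(n_atoms) + 4L]
  element <- trimws(substr(atom_lines, 32L, 34L))
  charge_code <- suppressWarnings(as.integer(trimws(substr(atom_lines, 37L, 39L))))
  charge <- unname(.sdf_charge_code[as.character(charge_code)])
  charge[is.na(charge)] <- 0
  bonds <- NULL
  if (n_bonds > 0L) {
    bond_lines <- lines[seq_len(n_bonds) + 4L + n_atoms]
    a1 <- as.integer(substr(bond_lines, 1L, 3L))
    a2 <- as.integer(substr(bond_lines, 4L, 6L))
    ord <- as.integer(substr(bond_lines, 7L, 9L))
    bonds <- tibble::tibble(a1 = pmin(a1, a2), a2 = pmax(a1, a2), order = ord)
  } else {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  # M  CHG property lines supersede the atom-column charge codes when present.
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0, n_atoms)
    for (ln in chg_lines) {
      flds <- scan(text = sub("^M  CHG", "", ln), what = integer(), quiet = TRUE)
      k <- flds[1L]
      for (i in seq_len(k)) {
        charge[flds[2L * i]] <- flds[2L * i + 1L]
      }
    }
  }
  degree <- rep(0L, n_atoms)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds$a1, bonds$a2), levels = seq_len(n_atoms)))
    degree <- as.integer(tab)
  }
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
    if (igraph::vcount(g) < n_atoms) g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    if (length(ring_edges)) {
      in_ring[unique(c(bonds$a1[ring_edges], bonds$a2[ring_edges]))] <- TRUE
    }
  }
  list(
    atoms = tibble::tibble(element = element, charge = charge,
                           degree = degree, in_ring = in_ring),
    bonds = bonds,
    n_atoms = n_atoms,
    n_bonds = nrow(bonds),
    net_charge = sum(charge)
  )
}

# Parse one SMILES string into a mol structure.  Memoised per session.
parse_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  cache_get_or(paste0("mol|", smiles), function() {
    sdf <- ob_convert("SMI", "SDF", paste0(smiles, " m"))
    lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
    if (length(lines) < 4L || !any(grepl("V2000", lines, fixed = TRUE))) {
      stop_parse(paste0("SMILES could not be parsed: '", smiles, "'"))
    }
    mol <- parse_molblock(lines)
    if (mol$n_atoms < 1L) stop_parse(paste0("SMILES has no atoms: '", smiles, "'"))
    mol$smiles <- canonical_smiles(smiles)
    mol
  })
}

# Canonicalise SMILES (vectorised).  Unparsable entries raise a parse error.
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character())
  key <- paste0("can|", smiles)
  miss <- vapply(key, function(k) is.null(.ilscreen_cache[[k]]), logical(1))
  if (any(miss)) {
    idx <- which(miss)
    src <- paste0(smiles[idx], " x", seq_along(idx), collapse = "\n")
    out <- ob_convert("SMI", "CAN", src)
    out_lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
    out_lines <- out_lines[nzchar(out_lines)]
    parts <- strsplit(out_lines, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) p[[2L]], character(1))
    got_can <- vapply(parts, function(p) p[[1L]], character(1))
    expect_id <- paste0("x", seq_along(idx))
    missing_ids <- setdiff(expect_id, got_id)
    if (length(missing_ids)) {
      bad <- smiles[idx][match(missing_ids, expect_id)]
      stop_parse(paste0("SMILES could not be parsed: '", bad[1L], "'"))
    }
    can <- got_can[match(expect_id, got_id)]
    for (i in seq_along(idx)) .ilscreen_cache[[key[idx[i]]]] <- can[i]
  }
  vapply(key, function(k) .ilscreen_cache[[k]], character(1), USE.NAMES = FALSE)
}

# Count matches of a SMARTS pattern in one SMILES (unique matches).
count_smarts <- function(smiles, pattern) {
  key <- paste0("smarts|", smiles, "|", pattern)
  cache_get_or(key, function() {
    n <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
      ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE)
    })
    as.numeric(n[[1L]])
  })
}

# OpenBabel physicochemical descriptors for one SMILES; returns a named
# numeric vector (MW, logP, TPSA, MR, HBA1, HBA2, HBD, nF).
ob_properties <- function(smiles) {
  key <- paste0("prop|", smiles)
  cache_get_or(key, function() {
    p <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
      ChemmineOB::prop_OB(m)
    })[[1L]]
    num <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
    out <- vapply(num, function(nm) {
      v <- suppressWarnings(as.numeric(p[[nm]]))
      if (length(v) != 1L || !is.finite(v)) 0 else v
    }, numeric(1))
    out
  })
}
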