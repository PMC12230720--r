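#' Chain models
#'
#' A `chain_model` is one polymer chain (protein or nucleic acid): an
#' ordered atom table plus the molecule kind and an optional domain
#' partition. NA chains are always rigid; a double-stranded NA supplied as a
#' single file can be kept as one rigid unit so base pairing survives
#' assembly.
#'
#' @param atoms data frame with columns `elety` (atom name), `resno`
#'   (residue number), `resid` (residue name), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstrom).
#' @param chain_id chain identifier.
#' @param kind `"protein"` or `"NA"`; classified automatically when `NULL`.
#' @param rigid logical; NA chains are forced rigid.
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(atoms, chain_id = "A", kind = NULL, rigid = FALSE) {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resno", "resid", "elesy", "x", "y", "z") %in%
                  names(atoms)))
  if (nrow(atoms) == 0) stop("chain has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (is.unsorted(atoms$resno)) atoms <- atoms[order(atoms$resno), ]
  obj <- structure(list(chain_id = chain_id, kind = kind, atoms = atoms,
                        rigid = rigid, domains = NULL),
                   class = "chain_model")
  if (is.null(kind)) obj$kind <- classify_chain(obj)
  if (obj$kind == "NA") obj$rigid <- TRUE
  obj
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s: %s, %d residues, %d atoms%s\n", x$chain_id,
              x$kind, n_residues(x), nrow(x$atoms),
              if (x$rigid) ", rigid" else ""))
  invisible(x)
}

#' @rdname chain_model
#' @param x object to test.
#' @export
is_chain_model <- function(x) inherits(x, "chain_model")

#' Number of residues in a chain
#' @param chain a [chain_model].
#' @export
n_residues <- function(chain) length(unique(chain$atoms$resno))

#' Atom coordinate matrix of a chain or complex
#' @param x a [chain_model] or [complex_model].
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x) UseMethod("coords")

#' @export
coords.chain_model <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' @export
coords.complex_model <- function(x)
  do.call(rbind, lapply(x$chains, coords))

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.nt <- c("A", "C", "G", "U", "T", "I", "DA", "DC", "DG", "DT", "DU", "DI")
.na_backbone <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
.prot_backbone <- c("N", "CA", "C", "O")

#' Classify a chain as protein or nucleic acid
#'
#' A chain is NA when the majority of its residues are standard nucleotides
#' (or carry P/O5'/C1' backbone atoms), protein otherwise. A genuinely mixed
#' chain (both classes above 25% of residues) raises an error and needs a
#' user override.
#'
#' @param chain a [chain_model].
#' @return `"protein"` or `"NA"`.
#' @export
classify_chain <- function(chain) {
  at <- chain$atoms
  res <- at[!duplicated(at$resno), ]
  if (nrow(res) < 1) stop("chain has no residues")
  resnames <- toupper(trimws(res$resid))
  is_nt <- resnames %in% .nt
  is_aa <- resnames %in% .aa3
  unknown <- !is_nt & !is_aa
  if (any(unknown)) {
    # fall back to backbone-atom content for nonstandard residue names
    for (i in which(unknown)) {
      an <- at$elety[at$resno == res$resno[i]]
      if (any(an %in% c("P", "O5'", "C1'"))) is_nt[i] <- TRUE
      else if (any(an %in% c("CA", "N"))) is_aa[i] <- TRUE
    }
  }
  f_nt <- mean(is_nt); f_aa <- mean(is_aa)
  if (f_nt > 0.25 && f_aa > 0.25)
    stop("mixed chain (", round(100 * f_aa), "% amino acid, ",
         round(100 * f_nt), "% nucleotide): set `kind` explicitly")
  if (f_nt > f_aa) "NA" else "protein"
}

#' Read chain structures from a PDB or mmCIF file
#'
#' Parses all polymer chains; HETATM-only files are rejected. When
#' `rigid_unit = TRUE` a multi-chain file (e.g. a double-stranded NA duplex)
#' is returned as a single rigid [chain_model] so that base pairing is
#' preserved through assembly; residues of the second and later chains are
#' renumbered to follow the first.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param rigid_unit treat the whole file as one rigid unit.
#' @return List of [chain_model] objects (length 1 when `rigid_unit`).
#' @export
read_chains <- function(path, rigid_unit = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("format error: no ATOM records (no polymer chains)")
  if (!is.null(at$insert) && any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported; renumber the input")
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    substr(trimws(at$elety[is.na(at$elesy) | at$elesy == ""]), 1, 1)
  at <- at[toupper(at$elesy) != "H", , drop = FALSE]  # heavy atoms only
  mk <- function(sub, id) {
    chain_model(data.frame(elety = trimws(sub$elety), resno = sub$resno,
                           resid = trimws(sub$resid),
                           elesy = toupper(trimws(sub$elesy)),
                           x = sub$x, y = sub$y, z = sub$z,
                           stringsAsFactors = FALSE),
                chain_id = id)
  }
  ids <- unique(at$chain)
  if (rigid_unit && length(ids) >= 1) {
    parts <- lapply(ids, function(id) at[at$chain == id, , drop = FALSE])
    off <- 0
    for (i in seq_along(parts)) {
      r <- parts[[i]]$resno
      parts[[i]]$resno <- r - min(r) + 1 + off
      off <- max(parts[[i]]$resno)
    }
    ch <- mk(do.call(rbind, parts), ids[1])
    ch$rigid <- TRUE
    return(list(ch))
  }
  lapply(ids, function(id) mk(at[at$chain == id, , drop = FALSE], id))
}

#' Apply a rigid-body pose to a chain
#'
#' Coordinates are rotated about the chain's center of mass and then
#' translated; internal geometry is untouched.
#'
#' @param chain a [chain_model].
#' @param p a [pose].
#' @param center optional rotation center (defaults to the chain's
#'   center of mass).
#' @return The transformed [chain_model].
#' @export
apply_pose <- function(chain, p, center = NULL) {
  stopifnot(is_chain_model(chain), inherits(p, "pose"))
  xyz <- coords(chain)
  if (is.null(center)) center <- colMeans(xyz)
  R <- pose_rotation_matrix(p)
  new <- sweep(xyz, 2, center) %*% t(R)
  new <- sweep(new, 2, center + p$t, "+")
  chain$atoms$x <- new[, 1]; chain$atoms$y <- new[, 2]; chain$atoms$z <- new[, 3]
  chain
}

#' Radius of gyration of a point set
#'
#' Square root of the mean (weighted) squared distance to the (weighted)
#' centroid.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param weights optional nonnegative weights (masses).
#' @export
radius_of_gyration <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1) stop("need at least one point")
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  w <- weights / sum(weights)
  ctr <- colSums(xyz * w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  rg <- sqrt(sum(w * d2))
  if (rg == 0 && nrow(xyz) > 1) warning("all points coincident: Rg = 0")
  rg
}

#' Complex models
#'
#' A set of placed chains in a common (map) physical frame, with optional
#' per-chain fit provenance.
#'
#' @param chains list of [chain_model] objects with unique chain ids.
#' @param provenance optional named list of per-chain fit scores.
#' @export
complex_model <- function(chains, provenance = NULL) {
  stopifnot(is.list(chains), length(chains) > 0,
            all(vapply(chains, is_chain_model, TRUE)))
  ids <- vapply(chains, function(c) c$chain_id, "")
  if (anyDuplicated(ids)) stop("duplicate chain ids: ", ids[duplicated(ids)][1])
  names(chains) <- ids
  structure(list(chains = chains, provenance = provenance),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> %d chains (%s)\n", length(x$chains),
              paste(vapply(x$chains, function(c)
                paste0(c$chain_id, ":", c$kind), ""), collapse = ", ")))
  invisible(x)
}

#' @rdname complex_model
#' @param x object to test.
#' @export
is_complex_model <- function(x) inherits(x, "complex_model")

#' Write a complex as a PDB file
#'
#' Chain ids are preserved; per-chain fit scores, when supplied, are
#' recorded in a REMARK block.
#'
#' @param model a [complex_model].
#' @param path output path.
#' @param scores optional named list / data frame of per-chain scores for
#'   the REMARK block.
#' @export
write_complex_pdb <- function(model, path, scores = NULL) {
  stopifnot(is_complex_model(model))
  lines <- character(0)
  if (!is.null(scores)) {
    lines <- c(lines, "REMARK 3  PER-CHAIN FIT SCORES")
    for (nm in names(scores))
      lines <- c(lines, sprintf("REMARK 3  CHAIN %s %s", nm,
                                paste(sprintf("%s=%.4f",
                                              names(scores[[nm]]),
                                              unlist(scores[[nm]])),
                                      collapse = " ")))
  }
  serial <- 0L
  for (ch in model$chains) {
    at <- ch$atoms
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      nm <- at$elety[i]
      # PDB atom-name column rules: element right-aligned in cols 13-14
      nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nmfmt, at$resid[i], substr(ch$chain_id, 1, 1),
        at$resno[i] %% 10000L, at$x[i], at$y[i], at$z[i], 1, 0, at$elesy[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Partition a protein chain into structural domains
#'
#' With explicit `boundaries` the chain is split at those residue numbers
#' (each boundary starts a new domain). Otherwise a simple automatic parser
#' is used: spectral bisection of the C-alpha contact graph (8 Angstrom
#' cutoff), accepted while both parts keep at least `min_part` residues and
#' the inter-part contact density is below `density_ratio` times the
#' intra-part density, recursively. Intended as a pragmatic stand-in for a
#' full domain parser; user-supplied boundaries always take precedence.
#' Fragments below `min_domain` residues are merged into their neighbor.
#'
#' @param chain a protein [chain_model].
#' @param boundaries optional increasing residue numbers at which to split.
#' @param min_domain minimum residues per domain (default 20).
#' @param min_part minimum residues per part for an automatic split.
#' @param contact_cutoff C-alpha contact distance, Angstrom.
#' @param density_ratio maximum inter/intra contact-density ratio for an
#'   accepted split.
#' @return A `domain_partition`: data frame of residue intervals
#'   (`start`, `end`, `domain`), jointly covering the chain.
#' @export
partition_domains <- function(chain, boundaries = NULL, min_domain = 20,
                              min_part = 60, contact_cutoff = 8,
                              density_ratio = 0.1) {
  stopifnot(is_chain_model(chain))
  if (chain$kind != "protein") stop("domain partition applies to protein chains")
  resnos <- sort(unique(chain$atoms$resno))
  lo <- min(resnos); hi <- max(resnos)
  if (!is.null(boundaries)) {
    boundaries <- sort(unique(as.integer(boundaries)))
    if (any(boundaries <= lo) || any(boundaries > hi))
      stop("boundaries outside the residue range (", lo, ", ", hi, "]")
    starts <- c(lo, boundaries)
    ends <- c(boundaries - 1L, hi)
    seg <- data.frame(start = starts, end = ends, domain = seq_along(starts))
    return(structure(seg, class = c("domain_partition", "data.frame")))
  }
  ca <- chain$atoms[chain$atoms$elety == "CA", , drop = FALSE]
  ca <- ca[match(resnos, ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  split_rec <- function(idx) {
    if (length(idx) < 2 * min_part) return(list(idx))
    sub <- xyz[idx, , drop = FALSE]
    A <- as.matrix(dist(sub)) < contact_cutoff
    diag(A) <- FALSE
    # Fiedler vector of the graph Laplacian
    L <- diag(rowSums(A)) - A
    ev <- eigen(L, symmetric = TRUE)
    f <- ev$vectors[, ncol(ev$vectors) - 1]
    # convert the spectral sign pattern into a single sequence split point
    best_k <- NA; best_mis <- Inf
    s <- sign(f)
    for (k in min_part:(length(idx) - min_part)) {
      mis <- sum(s[1:k] != s[1]) + sum(s[(k + 1):length(idx)] != s[length(idx)])
      if (s[1] != s[length(idx)] && mis < best_mis) { best_mis <- mis; best_k <- k }
    }
    if (is.na(best_k)) return(list(idx))
    i1 <- idx[1:best_k]; i2 <- idx[(best_k + 1):length(idx)]
    n1 <- length(i1); n2 <- length(i2)
    Afull <- A
    inter <- sum(Afull[1:best_k, (best_k + 1):length(idx)])
    intra <- (sum(Afull[1:best_k, 1:best_k]) / 2 +
                sum(Afull[(best_k + 1):length(idx),
                          (best_k + 1):length(idx)]) / 2)
    inter_den <- inter / (n1 * n2)
    intra_den <- intra / (choose(n1, 2) + choose(n2, 2))
    if (intra_den <= 0 || inter_den / intra_den >= density_ratio)
      return(list(idx))
    c(split_rec(i1), split_rec(i2))
  }
  parts <- split_rec(seq_len(n))
  seg <- data.frame(start = vapply(parts, function(p) resnos[min(p)], 0),
                    end = vapply(parts, function(p) resnos[max(p)], 0))
  seg <- seg[order(seg$start), ]
  # merge fragments below the minimum size into the nearest neighbor
  while (nrow(seg) > 1 && any(seg$end - seg$start + 1 < min_domain)) {
    i <- which.min(seg$end - seg$start)
    j <- if (i == 1) 2 else i - 1
    seg$start[j] <- min(seg$start[c(i, j)])
    seg$end[j] <- max(seg$end[c(i, j)])
    seg <- seg[-i, , drop = FALSE]
  }
  seg$domain <- seq_len(nrow(seg))
  rownames(seg) <- NULL
  structure(seg, class = c("domain_partition", "data.frame"))
}
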