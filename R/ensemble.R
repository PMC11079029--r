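# Multi-conformer structure handling: the structure_ensemble container,
# PDB I/O (via bio3d), least-squares superposition, ensemble r.m.s.d.
# statistics and label-to-amide distance extraction.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure ensemble
#'
#' A \code{structure_ensemble} holds an ordered set of conformers that
#' share one atom inventory.  Coordinates are stored in the bio3d
#' "xyz" convention: one row per conformer, columns x1,y1,z1,x2,...
#'
#' @param atoms data.frame with columns \code{chain}, \code{resid}
#'   (author numbering, integer), \code{resname}, \code{elety}
#'   (atom name, e.g. "CA").
#' @param xyz numeric matrix, one row per conformer, \code{3*nrow(atoms)}
#'   columns.
#' @return An object of class \code{structure_ensemble}.
#' @export
structure_ensemble <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resid", "resname", "elety")
  if (!all(need %in% names(atoms))) {
    stopf("atoms must have columns %s", paste(need, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stopf("xyz has %d columns; expected %d (3 per atom)",
          ncol(xyz), 3L * nrow(atoms))
  }
  check_finite(xyz, "ensemble coordinates")
  key <- paste(atoms$chain, atoms$resid, atoms$elety)
  if (anyDuplicated(key)) stopf("duplicate (chain, residue, atom) entries")
  structure(list(atoms = atoms, xyz = xyz), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d conformer(s), %d atoms, %d residue(s)\n",
              n_conformers(x), nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ens A \code{structure_ensemble}.
#' @return Integer count.
#' @export
n_conformers <- function(ens) nrow(ens$xyz)

#' Coordinates of one conformer
#' @param ens A \code{structure_ensemble}.
#' @param i Conformer index (1-based).
#' @return Numeric matrix, one row per atom, columns x, y, z.
#' @export
conformer_coords <- function(ens, i = 1L) {
  if (i < 1L || i > n_conformers(ens)) stopf("conformer index out of range")
  matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
}

set_conformer_coords <- function(ens, i, coords) {
  ens$xyz[i, ] <- as.numeric(t(coords))
  ens
}

#' Read a multi-MODEL PDB file into a structure ensemble
#'
#' Author residue numbering is preserved; altloc records other than
#' blank or 'A' are dropped with a warning; hydrogens are retained.
#' In strict mode an inconsistent atom inventory across MODELs is an
#' error; in lenient mode the intersection of inventories is kept.
#'
#' @param path Path to a PDB file with one or more MODEL blocks.
#' @param lenient If \code{TRUE}, reconcile differing MODELs by
#'   intersecting their atom inventories instead of failing.
#' @return A \code{structure_ensemble}.
#' @export
read_ensemble <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (!lenient) {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    atoms <- pdb$atom
    keep <- atoms$alt %in% c("", "A") | is.na(atoms$alt)
    if (!all(keep)) {
      warnf("dropping %d altloc records (kept blank/'A')", sum(!keep))
    }
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    idx <- which(keep)
    cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
    ens_atoms <- data.frame(chain = atoms$chain[keep],
                            resid = atoms$resno[keep],
                            resname = atoms$resid[keep],
                            elety = atoms$elety[keep],
                            stringsAsFactors = FALSE)
    ens_atoms$chain[is.na(ens_atoms$chain)] <- "A"
    return(structure_ensemble(ens_atoms, xyz[, cols, drop = FALSE]))
  }
  # lenient: parse MODEL blocks individually and intersect inventories
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  models <- lapply(seq_along(starts), function(k) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(lines[starts[k]:ends[k]], tf)
    read_ensemble(tf, lenient = FALSE)
  })
  keys <- lapply(models, function(m)
    paste(m$atoms$chain, m$atoms$resid, m$atoms$elety))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) stopf("no common atoms across MODELs")
  if (any(vapply(keys, length, 1L) != length(common))) {
    warnf("MODEL atom inventories differ; intersecting to %d atoms",
          length(common))
  }
  sub <- lapply(models, function(m) {
    idx <- match(common, paste(m$atoms$chain, m$atoms$resid, m$atoms$elety))
    list(atoms = m$atoms[idx, , drop = FALSE],
         coords = conformer_coords(m, 1L)[idx, , drop = FALSE])
  })
  xyz <- do.call(rbind, lapply(sub, function(s) as.numeric(t(s$coords))))
  structure_ensemble(sub[[1]]$atoms, xyz)
}

#' Write a structure ensemble as a multi-MODEL PDB file
#' @param ens A \code{structure_ensemble}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ensemble <- function(ens, path) {
  bio3d::write.pdb(pdb = NULL, file = path, xyz = ens$xyz,
                   resno = ens$atoms$resid, resid = ens$atoms$resname,
                   elety = ens$atoms$elety, chain = ens$atoms$chain)
  invisible(path)
}

#' Define an atom selection
#'
#' @param ranges data.frame with columns \code{chain}, \code{start},
#'   \code{end} (residue ranges, author numbering, inclusive), or NULL
#'   for all residues.
#' @param atoms Atom class: backbone (N, CA, C, O), heavy
#'   (non-hydrogen) or all.
#' @return An object of class \code{selection}.
#' @export
selection <- function(ranges = NULL, atoms = c("backbone", "heavy", "all")) {
  atoms <- match.arg(atoms)
  if (!is.null(ranges)) {
    ranges <- as.data.frame(ranges, stringsAsFactors = FALSE)
    if (!all(c("chain", "start", "end") %in% names(ranges))) {
      stopf("ranges needs columns chain, start, end")
    }
  }
  structure(list(ranges = ranges, atoms = atoms), class = "selection")
}

#' Parse a selection string like "A:146-221,B:575-582,B:586-590"
#' @param text Selection text; comma-separated \code{chain:start-end} items.
#' @param atoms Atom class, as in \code{\link{selection}}.
#' @return A \code{selection}.
#' @export
parse_selection <- function(text, atoms = "backbone") {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*([^:]+):(\\d+)-(\\d+)\\s*$", parts))
  if (any(vapply(m, length, 1L) != 4L)) stopf("cannot parse selection '%s'", text)
  ranges <- do.call(rbind, lapply(m, function(g)
    data.frame(chain = g[2], start = as.integer(g[3]), end = as.integer(g[4]),
               stringsAsFactors = FALSE)))
  selection(ranges, atoms)
}

is_hydrogen <- function(elety) grepl("^[0-9]*H", elety)

#' Resolve a selection to atom indices of an ensemble
#' @param ens A \code{structure_ensemble}.
#' @param sel A \code{selection}.
#' @return Integer atom indices.
#' @export
resolve_selection <- function(ens, sel) {
  a <- ens$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$ranges)) {
    keep <- rep(FALSE, nrow(a))
    for (k in seq_len(nrow(sel$ranges))) {
      r <- sel$ranges[k, ]
      keep <- keep | (a$chain == r$chain & a$resid >= r$start & a$resid <= r$end)
    }
  }
  keep <- keep & switch(sel$atoms,
                        backbone = a$elety %in% BACKBONE_ATOMS,
                        heavy = !is_hydrogen(a$elety),
                        all = TRUE)
  which(keep)
}

#' Optimal least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1) and translation that
#' minimise the r.m.s.d. of \code{mobile} onto \code{reference} over
#' the selected atoms.
#'
#' @param mobile,reference Either n x 3 coordinate matrices or
#'   single-conformer coordinate sets from \code{conformer_coords}.
#' @param sel Optional integer atom indices over which to fit (the
#'   transform is still returned for application to all atoms).
#' @return List with \code{rotation} (3 x 3), \code{translation}
#'   (length 3; transform is \code{x \%*\% t(R) + t}), and \code{rmsd}
#'   (Angstrom, over the fitted atoms).
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  m <- as.matrix(mobile); r <- as.matrix(reference)
  if (!is.null(sel)) { mf <- m[sel, , drop = FALSE]; rf <- r[sel, , drop = FALSE] }
  else { mf <- m; rf <- r }
  if (nrow(mf) != nrow(rf)) stopf("coordinate sets differ in size")
  if (nrow(mf) < 3L) stopf("need at least 3 atoms for superposition")
  cm <- colMeans(mf); cr <- colMeans(rf)
  a <- sweep(mf, 2, cm); b <- sweep(rf, 2, cr)
  h <- crossprod(a, b)                      # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot, translation = as.numeric(cr), center = as.numeric(cm),
       rmsd = rmsd)
}

apply_superposition <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center) %*% t(fit$rotation), 2, fit$translation, "+")
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Ensemble coordinate r.m.s.d. statistics
#'
#' Computes the ensemble precision over a residue selection, reported
#' for both the backbone (N, CA, C, O) and heavy-atom classes of the
#' selected residues.  \code{to_mean} iteratively superposes every
#' conformer onto the evolving mean structure (two passes) and averages
#' the per-conformer r.m.s.d. to the mean; \code{pairwise} averages
#' over all ordered conformer pairs after pairwise superposition.
#' Superposition uses the backbone atoms of the selection.
#'
#' @param ens A \code{structure_ensemble} with at least 2 conformers.
#' @param sel A \code{selection} (its atom class is ignored; backbone
#'   and heavy classes of its residue ranges are reported).
#' @param mode "to_mean" or "pairwise".
#' @return Named numeric vector \code{c(backbone_rmsd, heavy_rmsd)} in
#'   Angstrom.
#' @export
ensemble_rmsd <- function(ens, sel = selection(), mode = c("to_mean", "pairwise")) {
  mode <- match.arg(mode)
  if (n_conformers(ens) < 2L) stopf("need at least 2 conformers")
  bb_idx <- resolve_selection(ens, selection(sel$ranges, "backbone"))
  hv_idx <- resolve_selection(ens, selection(sel$ranges, "heavy"))
  if (length(bb_idx) < 3L) stopf("selection resolves to <3 backbone atoms")
  confs <- lapply(seq_len(n_conformers(ens)), function(i) conformer_coords(ens, i))
  one_class <- function(confs, fit_idx, rep_idx, mode) {
    if (mode == "to_mean") {
      # pre-align onto the first conformer so the result is independent
      # of arbitrary rigid placements, then iterate superposition onto
      # the evolving mean structure until it stops moving
      cur <- lapply(confs, function(x) {
        f <- kabsch_superpose(x[fit_idx, , drop = FALSE],
                              confs[[1]][fit_idx, , drop = FALSE])
        apply_superposition(x, f)
      })
      prev_mean <- NULL
      for (pass in 1:50) {
        mean_fit <- Reduce(`+`, lapply(cur, function(x) x[fit_idx, , drop = FALSE])) /
          length(cur)
        if (!is.null(prev_mean) &&
            max(abs(mean_fit - prev_mean)) < 1e-10) break
        prev_mean <- mean_fit
        cur <- lapply(cur, function(x) {
          f <- kabsch_superpose(x[fit_idx, , drop = FALSE], mean_fit)
          apply_superposition(x, f)
        })
      }
      mean_rep <- Reduce(`+`, lapply(cur, function(x) x[rep_idx, , drop = FALSE])) /
        length(cur)
      mean(vapply(cur, function(x)
        rmsd_between(x[rep_idx, , drop = FALSE], mean_rep), 1.0))
    } else {
      n <- length(confs)
      pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
      pairs <- pairs[pairs$i != pairs$j, ]
      mean(mapply(function(i, j) {
        f <- kabsch_superpose(confs[[i]][fit_idx, , drop = FALSE],
                              confs[[j]][fit_idx, , drop = FALSE])
        moved <- apply_superposition(confs[[i]], list(rotation = f$rotation,
                                                      translation = f$translation,
                                                      center = f$center))
        rmsd_between(moved[rep_idx, , drop = FALSE],
                     confs[[j]][rep_idx, , drop = FALSE])
      }, pairs$i, pairs$j))
    }
  }
  c(backbone_rmsd = one_class(confs, bb_idx, bb_idx, mode),
    heavy_rmsd = one_class(confs, bb_idx, hv_idx, mode))
}

#' Spin-label site description
#'
#' @param residue_id Labeled residue (author numbering).
#' @param chain Chain identifier.
#' @param position_model "CB_point" places the unpaired electron at the
#'   residue's CB atom; "offset_point" extends a fixed arm outward
#'   along the CA->CB direction to mimic a nitroxide tether.
#' @param offset Arm length in Angstrom (offset_point only).
#' @return An object of class \code{label_site}.
#' @export
label_site <- function(residue_id, chain = "A",
                       position_model = c("CB_point", "offset_point"),
                       offset = 6) {
  position_model <- match.arg(position_model)
  structure(list(residue_id = as.integer(residue_id), chain = chain,
                 position_model = position_model, offset = offset),
            class = "label_site")
}

atom_index <- function(ens, chain, resid, elety) {
  which(ens$atoms$chain == chain & ens$atoms$resid == resid &
          ens$atoms$elety == elety)
}

label_position <- function(coords, ens, site) {
  icb <- atom_index(ens, site$chain, site$residue_id, "CB")
  if (length(icb) != 1L) stopf("label residue %d has no CB atom", site$residue_id)
  cb <- coords[icb, ]
  if (site$position_model == "CB_point") return(cb)
  ica <- atom_index(ens, site$chain, site$residue_id, "CA")
  if (length(ica) != 1L) stopf("label residue %d has no CA atom", site$residue_id)
  ca <- coords[ica, ]
  ca + vunit(cb - ca) * (vnorm(cb - ca) + site$offset)
}

#' Build amide proton positions from backbone geometry
#'
#' For residues lacking an amide H, the proton is placed in the peptide
#' plane 1.02 Angstrom from N along the direction bisecting the
#' C(i-1)-N and CA-N bonds (reversed).  The chain's first residue has
#' no preceding carbonyl and is skipped.
#'
#' @param ens A \code{structure_ensemble}.
#' @param conformer Conformer index.
#' @param r_nh N-H bond length in Angstrom.
#' @return data.frame with chain, resid and the H coordinates (columns
#'   hx, hy, hz) plus the matching N coordinates (nx, ny, nz).
#' @export
amide_h_positions <- function(ens, conformer = 1L, r_nh = 1.02) {
  coords <- conformer_coords(ens, conformer)
  a <- ens$atoms
  res <- unique(a[a$elety == "N", c("chain", "resid")])
  out <- list()
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; ri <- res$resid[k]
    i_n <- atom_index(ens, ch, ri, "N")
    i_h <- atom_index(ens, ch, ri, "H")
    if (length(i_h) == 0L) i_h <- atom_index(ens, ch, ri, "HN")
    if (length(i_h) == 1L) {
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, resid = ri,
        nx = coords[i_n, 1], ny = coords[i_n, 2], nz = coords[i_n, 3],
        hx = coords[i_h, 1], hy = coords[i_h, 2], hz = coords[i_h, 3],
        stringsAsFactors = FALSE)
      next
    }
    i_ca <- atom_index(ens, ch, ri, "CA")
    i_cp <- atom_index(ens, ch, ri - 1L, "C")
    if (length(i_n) != 1L || length(i_ca) != 1L || length(i_cp) != 1L) next
    n <- coords[i_n, ]; ca <- coords[i_ca, ]; cp <- coords[i_cp, ]
    hdir <- -(vunit(cp - n) + vunit(ca - n))
    h <- n + vunit(hdir) * r_nh
    out[[length(out) + 1L]] <- data.frame(
      chain = ch, resid = ri, nx = n[1], ny = n[2], nz = n[3],
      hx = h[1], hy = h[2], hz = h[3], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stopf("no amide protons resolvable")
  do.call(rbind, out)
}

#' Distances from a spin-label site to target atoms
#'
#' @param ens A \code{structure_ensemble}.
#' @param site A \code{label_site}.
#' @param targets Either an atom name (default "H", amide protons built
#'   from backbone geometry when absent) or a data.frame with columns
#'   chain, resid, elety.
#' @return data.frame with chain, resid, conformer and distance
#'   (Angstrom); unresolvable targets carry NA distances.
#' @export
label_distances <- function(ens, site, targets = "H") {
  nc <- n_conformers(ens)
  res <- list()
  for (i in seq_len(nc)) {
    coords <- conformer_coords(ens, i)
    lab <- label_position(coords, ens, site)
    if (is.character(targets) && length(targets) == 1L && targets == "H") {
      hp <- amide_h_positions(ens, i)
      d <- sqrt((hp$hx - lab[1])^2 + (hp$hy - lab[2])^2 + (hp$hz - lab[3])^2)
      res[[i]] <- data.frame(chain = hp$chain, resid = hp$resid,
                             conformer = i, distance = d,
                             stringsAsFactors = FALSE)
    } else {
      tg <- as.data.frame(targets, stringsAsFactors = FALSE)
      d <- vapply(seq_len(nrow(tg)), function(k) {
        idx <- atom_index(ens, tg$chain[k], tg$resid[k], tg$elety[k])
        if (length(idx) != 1L) return(NA_real_)
        vnorm(coords[idx, ] - lab)
      }, 1.0)
      res[[i]] <- data.frame(chain = tg$chain, resid = tg$resid,
                             conformer = i, distance = d,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (anyNA(out$distance)) warnf("%d unresolvable target atoms flagged NA",
                                 sum(is.na(out$distance)) / nc)
  out
}
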