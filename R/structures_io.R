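# ---- Structure container -----------------------------------------------

#' Atomic structure container
#'
#' A `Structure` holds an atomic model as a data frame of atoms with original
#' PDB-style numbering.  Columns: `atom` (atom name), `element`, `resid`
#' (integer residue number), `ins` (insertion code, "" if none), `resname`,
#' `chain`, and coordinates `x`, `y`, `z` in Angstrom.
#'
#' @param atoms data.frame with the columns listed above.
#' @param label character label carried through analyses.
#' @return object of class `Structure`.
#' @export
structure_new <- function(atoms, label = "structure") {
  req <- c("atom", "element", "resid", "ins", "resname", "chain",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("Structure atoms missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  atoms$resid <- as.integer(atoms$resid)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in Structure")
  key <- paste(atoms$chain, atoms$resid, atoms$ins, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, insertion, atom) records in Structure")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure '%s': %d atoms, %d residues, chains %s>\n",
              x$label, nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

#' Coordinates of a Structure or ReducedStructure as an n x 3 matrix
#' @param s Structure or ReducedStructure.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  df <- if (inherits(s, "Structure")) s$atoms else s$beads
  cbind(x = df$x, y = df$y, z = df$z)
}

#' Replace the coordinates of a structure-like object
#' @param s Structure or ReducedStructure.
#' @param xyz n x 3 matrix.
#' @return object of the same class with new coordinates.
#' @export
set_coords <- function(s, xyz) {
  slot <- if (inherits(s, "Structure")) "atoms" else "beads"
  stopifnot(nrow(xyz) == nrow(s[[slot]]))
  s[[slot]]$x <- xyz[, 1]; s[[slot]]$y <- xyz[, 2]; s[[slot]]$z <- xyz[, 3]
  s
}

#' Number of residues in a structure
#' @param s Structure.
#' @export
n_residues <- function(s) {
  df <- if (inherits(s, "Structure")) s$atoms else s$beads
  length(unique(paste(df$chain, df$resid, if (!is.null(df$ins)) df$ins else "")))
}

#' Subset a Structure by a logical or integer atom index
#' @param s Structure.
#' @param idx logical or integer index into the atom table.
#' @export
subset_atoms <- function(s, idx) {
  at <- s$atoms[idx, , drop = FALSE]
  rownames(at) <- NULL
  structure(list(atoms = at, label = s$label), class = "Structure")
}

#' Centroid (geometric center) of a structure
#' @param s Structure or ReducedStructure.
#' @export
centroid <- function(s) colMeans(coords(s))

# ---- PDB I/O ------------------------------------------------------------

.guess_element <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "NA", "BR", "SE"),
         substr(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), 1, 2),
         toupper(substr(nm, 1, 1)))
}

#' Read a PDB file
#'
#' Minimal fixed-column PDB reader.  Keeps ATOM records (and HETATM on
#' request), drops hydrogens and waters, keeps the highest-occupancy
#' alternate conformer, preserves author residue numbering.
#'
#' @param path path to a PDB file.
#' @param chain optional chain selector (character vector).
#' @param model model number to keep (default 1; models delimited by
#'   MODEL/ENDMDL, files without MODEL records are treated as model 1).
#' @param hetero keep HETATM records (cofactors); waters are always dropped.
#' @param label label for the returned Structure (default: file base name).
#' @return a [structure_new()] Structure.
#' @export
read_pdb <- function(path, chain = NULL, model = 1L, hetero = FALSE,
                     label = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cur_model <- 1L
  keep <- logical(length(lines))
  model_no <- integer(length(lines))
  in_model <- 1L
  for (i in seq_along(lines)) {       # assign model numbers
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      in_model <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(in_model)) in_model <- cur_model + 1L
      cur_model <- in_model
    }
    model_no[i] <- in_model
    keep[i] <- startsWith(r, "ATOM") || (hetero && startsWith(r, "HETATM"))
  }
  keep <- keep & model_no == model
  lines <- lines[keep]
  if (!length(lines)) stop("format error: no atom records parsed from ", path)

  f <- function(a, b) trimws(substr(lines, a, b))
  at <- data.frame(
    atom    = f(13, 16),
    altloc  = f(17, 17),
    resname = f(18, 20),
    chain   = f(22, 22),
    resid   = suppressWarnings(as.integer(f(23, 26))),
    ins     = f(27, 27),
    x       = suppressWarnings(as.numeric(f(31, 38))),
    y       = suppressWarnings(as.numeric(f(39, 46))),
    z       = suppressWarnings(as.numeric(f(47, 54))),
    occ     = suppressWarnings(as.numeric(f(55, 60))),
    element = f(77, 78),
    stringsAsFactors = FALSE)
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z) || anyNA(at$resid))
    stop("format error: unparseable coordinate fields in ", path)
  at$element[at$element == ""] <- .guess_element(at$atom[at$element == ""])
  at$occ[is.na(at$occ)] <- 1

  at <- at[at$resname != "HOH", , drop = FALSE]
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("selection error: no atoms left after selection")

  # highest-occupancy alternate conformer, ties to first altloc seen
  key <- paste(at$chain, at$resid, at$ins, at$atom)
  if (anyDuplicated(key)) {
    ord <- order(key, -at$occ, at$altloc)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resid, at$ins, at$atom)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  at$altloc <- NULL; at$occ <- NULL
  structure_new(at, label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Structure to a PDB file
#' @param s Structure.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  at <- s$atoms
  ser <- seq_len(nrow(at)) %% 100000L
  nm <- ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom)
  rl <- sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                ser, nm, substr(at$resname, 1, 3), substr(at$chain, 1, 1),
                at$resid %% 10000L, ifelse(at$ins == "", " ", at$ins),
                at$x, at$y, at$z, 1, 0, at$element)
  writeLines(c(rl, "END"), path)
  invisible(path)
}

# ---- regions ------------------------------------------------------------

#' Flexible-region specification
#'
#' Named residue ranges (for pruning and buried-surface decomposition) plus a
#' list of boundary residues used by the docking pose filter.  A RecA-style
#' example: Nter = 1-37, L1 = 156-165, L2 = 194-210, Cterm = 329-333 with
#' boundary residues 38, 156, 165, 194, 210.
#'
#' @param ranges named list; each element is `c(start, end)` or a list of
#'   such ranges.
#' @param boundary integer vector of single boundary residues.
#' @param chain optional chain restriction.
#' @return object of class `RegionSpec`.
#' @export
region_spec <- function(ranges = list(), boundary = integer(), chain = NULL) {
  norm <- lapply(ranges, function(r) {
    if (is.numeric(r) && length(r) == 2) r <- list(r)
    lapply(r, function(p) {
      p <- as.integer(p)
      if (length(p) != 2 || p[1] > p[2]) stop("bad range in RegionSpec")
      p
    })
  })
  for (nm in names(norm)) {          # non-overlap within a name
    res <- unlist(lapply(norm[[nm]], function(p) p[1]:p[2]))
    if (anyDuplicated(res)) stop("overlapping ranges within region ", nm)
  }
  structure(list(ranges = norm, boundary = as.integer(boundary),
                 chain = chain), class = "RegionSpec")
}

#' Residue numbers covered by one region (or all regions) of a RegionSpec
#' @param spec RegionSpec.
#' @param name region name, or NULL for the union of all regions.
#' @export
region_residues <- function(spec, name = NULL) {
  rg <- if (is.null(name)) unlist(spec$ranges, recursive = FALSE)
        else spec$ranges[[name]]
  if (is.null(rg)) return(integer())
  sort(unique(unlist(lapply(rg, function(p) p[1]:p[2]))))
}

#' Remove flexible regions from a structure
#'
#' Deletes every residue falling in the spec's ranges; residues already
#' absent (e.g. disordered in the crystal) are silently skipped.
#'
#' @param s Structure.
#' @param spec RegionSpec.
#' @return pruned Structure.
#' @export
prune_regions <- function(s, spec) {
  res <- region_residues(spec)
  at <- s$atoms
  drop <- at$resid %in% res
  if (!is.null(spec$chain)) drop <- drop & at$chain %in% spec$chain
  out <- subset_atoms(s, !drop)
  if (n_residues(out) < 10)
    stop("degenerate-structure error: pruning left fewer than 10 residues")
  out$label <- paste0(s$label, "_core")
  out
}

#' Read a RegionSpec from a JSON config file
#'
#' Format: `{"ranges": {"Nter": [1,37], "L1": [156,165]},
#' "boundary": [38,156], "chain": null}`.
#' @param path JSON file.
#' @export
read_region_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_spec(ranges = as.list(cfg$ranges),
              boundary = cfg$boundary %||% integer(),
              chain = cfg$chain)
}

# ---- coarse graining ----------------------------------------------------

.BACKBONE <- c("N", "CA", "C", "O", "OXT")
.GAMMA    <- c("CB", "CG", "CG1", "CG2", "OG", "OG1", "SG")

#' Default bead mapping scheme
#'
#' One backbone bead (N, CA, C, O centroid) per residue plus up to two
#' side-chain beads split at the gamma position, giving roughly four heavy
#' atoms per bead for standard residues.  Side-chain beads of Asp/Glu carry
#' charge -1 and Lys/Arg +1 (on the distal bead).  Bead classes drive the
#' nonbonded parameter table: BB backbone, SCA apolar, SCP polar,
#' SCC charged.
#' @return a list with entries `id`, `charges`, `apolar`.
#' @export
default_bead_scheme <- function() {
  list(id = "bb+sc2",
       charges = c(ASP = -1, GLU = -1, LYS = +1, ARG = +1),
       apolar = c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "GLY"))
}

#' Reduce a structure to coarse-grained beads
#'
#' @param s Structure.
#' @param scheme mapping scheme, see [default_bead_scheme()].
#' @return object of class `ReducedStructure` with a `beads` data frame
#'   (`class`, `charge`, `resid`, `ins`, `resname`, `chain`, `x`, `y`, `z`,
#'   `natoms`).
#' @export
coarse_grain <- function(s, scheme = default_bead_scheme()) {
  at <- s$atoms
  rk <- paste(at$chain, at$resid, at$ins)
  out <- vector("list", length(unique(rk)))
  i <- 0
  for (k in unique(rk)) {
    sel <- at[rk == k, , drop = FALSE]
    rn <- sel$resname[1]
    bb <- sel[sel$atom %in% .BACKBONE, , drop = FALSE]
    sc <- sel[!sel$atom %in% .BACKBONE, , drop = FALSE]
    if (!nrow(bb)) bb <- sel          # fallback: centroid of everything
    beads <- list()
    beads[[1]] <- c(class = "BB", charge = 0, n = nrow(bb),
                    x = mean(bb$x), y = mean(bb$y), z = mean(bb$z))
    if (nrow(sc)) {
      prox <- sc[sc$atom %in% .GAMMA, , drop = FALSE]
      dist <- sc[!sc$atom %in% .GAMMA, , drop = FALSE]
      q <- unname(scheme$charges[rn]); if (is.na(q)) q <- 0
      cls <- if (q != 0) "SCC" else if (rn %in% scheme$apolar) "SCA" else "SCP"
      if (nrow(prox) && nrow(dist)) {
        beads[[2]] <- c(class = cls, charge = 0, n = nrow(prox),
                        x = mean(prox$x), y = mean(prox$y), z = mean(prox$z))
        beads[[3]] <- c(class = cls, charge = q, n = nrow(dist),
                        x = mean(dist$x), y = mean(dist$y), z = mean(dist$z))
      } else {
        beads[[2]] <- c(class = cls, charge = q, n = nrow(sc),
                        x = mean(sc$x), y = mean(sc$y), z = mean(sc$z))
      }
    }
    for (bi in seq_along(beads)) {
      b <- beads[[bi]]
      i <- i + 1
      out[[i]] <- data.frame(atom = if (bi == 1) "BB" else paste0("SC", bi - 1),
                             class = b[["class"]],
                             charge = as.numeric(b[["charge"]]),
                             resid = sel$resid[1], ins = sel$ins[1],
                             resname = rn, chain = sel$chain[1],
                             x = as.numeric(b[["x"]]), y = as.numeric(b[["y"]]),
                             z = as.numeric(b[["z"]]),
                             natoms = as.integer(b[["n"]]),
                             stringsAsFactors = FALSE)
    }
  }
  beads <- do.call(rbind, out[seq_len(i)])
  rownames(beads) <- NULL
  structure(list(beads = beads, scheme = scheme$id, label = s$label),
            class = "ReducedStructure")
}

#' @export
print.ReducedStructure <- function(x, ...) {
  cat(sprintf("<ReducedStructure '%s': %d beads (%s), total charge %+g>\n",
              x$label, nrow(x$beads), x$scheme, sum(x$beads$charge)))
  invisible(x)
}
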