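#' Load a protein structure from a PDB-format file
#'
#' Thin wrapper over [bio3d::read.pdb()] that applies the conventions
#' used for interface-contact analysis: the first model of a multi-model
#' file, waters removed, hydrogens removed by default, and for alternate
#' conformations only the highest-occupancy location of each atom kept.
#'
#' @param path Path to a PDB-format file.
#' @param keep_hydrogens Keep hydrogen atoms (default FALSE).
#' @return An object of class `structure_model`: a data frame of atoms
#'   with columns `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`,
#'   `o`, plus the source path as attribute.
#' @export
read_structure <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no atoms parsed from ", path)
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_hydrogens) {
    elem <- a$elesy
    is_h <- !is.na(elem) & trimws(elem) %in% c("H", "D")
    no_elem <- is.na(elem) | trimws(elem) == ""
    is_h[no_elem] <- grepl("^[0-9]*H", trimws(a$elety[no_elem]))
    a <- a[!is_h, , drop = FALSE]
  }
  # alternate locations: keep the highest-occupancy conformer per atom
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  if (nrow(a) == 0) stop("no atoms left after filtering in ", path)
  out <- a[, c("chain", "resno", "resid", "elety", "x", "y", "z", "o")]
  rownames(out) <- NULL
  attr(out, "source") <- path
  class(out) <- c("structure_model", "data.frame")
  out
}

# parse "A:89" or list(chain=, resno=) into a (chain, resno) pair
.parse_residue <- function(res) {
  if (is.list(res)) return(list(chain = res$chain, resno = res$resno))
  parts <- strsplit(as.character(res), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("residue must be 'chain:resno', got ", res)
  list(chain = parts[1], resno = as.integer(parts[2]))
}

.residue_atoms <- function(model, res) {
  r <- .parse_residue(res)
  a <- model[model$chain == r$chain & model$resno == r$resno, ,
             drop = FALSE]
  if (nrow(a) == 0)
    stop("residue ", r$chain, ":", r$resno, " not found in structure")
  a
}

#' Minimum inter-residue distance
#'
#' Minimum Euclidean distance over all atom pairs between two residues
#' (heavy atoms only unless hydrogens were kept at load time; optionally
#' side-chain atoms only).
#'
#' @param model A `structure_model` (see [read_structure()]).
#' @param res_a,res_b Residues as `"chain:resno"` strings or
#'   `list(chain=, resno=)`.
#' @param side_chain_only Restrict to side-chain atoms (exclude N, CA,
#'   C, O).
#' @param cutoff Contact cutoff in angstroms used for the `in_contact`
#'   flag.
#' @return A list with `res_a`, `res_b`, `distance` (angstroms) and
#'   `in_contact`.
#' @export
min_distance <- function(model, res_a, res_b, side_chain_only = FALSE,
                         cutoff = 5.0) {
  a <- .residue_atoms(model, res_a)
  b <- .residue_atoms(model, res_b)
  if (side_chain_only) {
    bb <- c("N", "CA", "C", "O", "OXT")
    a2 <- a[!(trimws(a$elety) %in% bb), , drop = FALSE]
    b2 <- b[!(trimws(b$elety) %in% bb), , drop = FALSE]
    if (nrow(a2) > 0) a <- a2
    if (nrow(b2) > 0) b <- b2
  }
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  d <- sqrt(min(dx^2 + dy^2 + dz^2))
  list(res_a = res_a, res_b = res_b, distance = d,
       in_contact = d <= cutoff)
}

#' Partner-chain residues within a distance shell of query residues
#'
#' Finds the residues of `partner_chain` whose minimum distance to any
#' of the query residues is at most `cutoff` (default 5 angstroms, the
#' shell used to nominate interface residues with the potential to
#' interact), deduplicated and sorted by residue number.
#'
#' @inheritParams min_distance
#' @param query_residues Character vector of `"chain:resno"` residues.
#' @param partner_chain Chain identifier to search.
#' @param cutoff Shell radius, angstroms.
#' @return Data frame with columns `chain`, `resno`, `resid`,
#'   `min_distance`.
#' @export
shell_residues <- function(model, query_residues, partner_chain,
                           cutoff = 5.0, side_chain_only = FALSE) {
  if (length(query_residues) == 0) stop("query_residues must be non-empty")
  partner <- model[model$chain == partner_chain, , drop = FALSE]
  if (nrow(partner) == 0)
    stop("no atoms on partner chain ", partner_chain)
  resnos <- sort(unique(partner$resno))
  hits <- lapply(resnos, function(rn) {
    dmin <- min(vapply(query_residues, function(q) {
      min_distance(model, q, list(chain = partner_chain, resno = rn),
                   side_chain_only = side_chain_only)$distance
    }, numeric(1)))
    data.frame(chain = partner_chain, resno = rn,
               resid = partner$resid[partner$resno == rn][1],
               min_distance = dmin)
  })
  out <- do.call(rbind, hits)
  out[out$min_distance <= cutoff, , drop = FALSE]
}
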