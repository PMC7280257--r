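# Active-site cluster extraction: any-atom contact search at a distance
# cutoff, whole-residue cluster assembly, and XYZ / QM-LED input-deck writers.

#' Find ligand-protein atom contacts within a distance cutoff
#'
#' Every (ligand atom, protein atom) pair at Euclidean distance less than or
#' equal to `cutoff` is reported. The protein side is restricted to the 20
#' standard amino acids; waters, ions and other heterogroups never count as
#' contacts. The boundary is inclusive: a pair at exactly `cutoff` is a
#' contact. Hydrogens are used if present in the file; none are added.
#'
#' @param structure a `structure_model` from [parse_structure()].
#' @param ligand three-letter heterogroup code of the ligand.
#' @param chain optional chain identifier restricting the ligand selection.
#' @param cutoff contact distance cutoff in Angstrom (default 3.5).
#' @return A data.frame of contacts sorted by distance, with the ligand atom,
#'   the protein atom, its residue identity and the distance in Angstrom.
#' @examples
#' txt <- make_toy_structure(n_residues = 3,
#'                           planted_min_distances = c(2.0, 3.4, 3.6), seed = 7)
#' mod <- parse_structure(txt)
#' con <- find_contacts(mod, ligand = "LIG", cutoff = 3.5)
#' unique(con$res_seq)  # residues 1 and 2 only
#' @export
find_contacts <- function(structure, ligand, chain = NULL, cutoff = 3.5) {
  stopifnot(inherits(structure, "structure_model"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    stop("cutoff must be a single non-negative distance in Angstrom", call. = FALSE)
  }
  a <- structure$atoms
  lig_sel <- a$record == "HETATM" & a$res_name == ligand
  if (!is.null(chain)) lig_sel <- lig_sel & a$chain == chain
  if (!any(lig_sel)) {
    hets <- sort(unique(a$res_name[a$record == "HETATM" &
                                     !(a$res_name %in% c("HOH", "WAT"))]))
    stop(sprintf("ligand '%s' not found; available heterogroups: %s",
                 ligand,
                 if (length(hets)) paste(hets, collapse = ", ") else "none"),
         call. = FALSE)
  }
  prot_sel <- a$record == "ATOM" & a$res_name %in% STANDARD_AA
  lig <- a[lig_sel, , drop = FALSE]
  prot <- a[prot_sel, , drop = FALSE]
  if (nrow(prot) == 0) {
    return(empty_contacts())
  }

  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # squared-distance matrix, ligand rows x protein columns
  d2 <- outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") - 2 * tcrossprod(lxyz, pxyz)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(empty_contacts())
  }
  res <- data.frame(
    ligand_serial = lig$serial[hit[, 1]],
    ligand_atom   = lig$name[hit[, 1]],
    protein_serial = prot$serial[hit[, 2]],
    protein_atom  = prot$name[hit[, 2]],
    res_name      = prot$res_name[hit[, 2]],
    chain         = prot$chain[hit[, 2]],
    res_seq       = prot$res_seq[hit[, 2]],
    i_code        = prot$i_code[hit[, 2]],
    distance      = sqrt(d2[hit]),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$distance, res$ligand_serial, res$protein_serial), ]
  rownames(res) <- NULL
  res
}

empty_contacts <- function() {
  data.frame(ligand_serial = integer(0), ligand_atom = character(0),
             protein_serial = integer(0), protein_atom = character(0),
             res_name = character(0), chain = character(0),
             res_seq = integer(0), i_code = character(0),
             distance = numeric(0), stringsAsFactors = FALSE)
}

#' Build a two-fragment active-site cluster around a ligand
#'
#' Residues with at least one atom within `cutoff` of any ligand atom are
#' taken whole (backbone and side chain, no capping); everything else is
#' omitted. The result partitions the cluster into a protein fragment and a
#' ligand fragment ready for QM-input emission.
#'
#' @inheritParams find_contacts
#' @return An object of class `cluster_geometry`: list with `protein` and
#'   `ligand` atom data.frames, `roster` (one row per contacting residue,
#'   sorted by residue number), `cutoff`, `ligand_code` and `source_id`.
#' @export
build_cluster <- function(structure, ligand, chain = NULL, cutoff = 3.5) {
  contacts <- find_contacts(structure, ligand, chain = chain, cutoff = cutoff)
  if (nrow(contacts) == 0) {
    stop(sprintf(paste("empty cluster: no residue has an atom within %.2f A of",
                       "ligand '%s' (cutoff too small or wrong ligand?)"),
                 cutoff, ligand), call. = FALSE)
  }
  a <- structure$atoms
  key <- function(chain, seq, icode) paste(chain, seq, icode, sep = "|")
  res_key <- unique(key(contacts$chain, contacts$res_seq, contacts$i_code))
  atom_key <- key(a$chain, a$res_seq, a$i_code)
  prot <- a[a$record == "ATOM" & atom_key %in% res_key, , drop = FALSE]

  lig_sel <- a$record == "HETATM" & a$res_name == ligand
  if (!is.null(chain)) lig_sel <- lig_sel & a$chain == chain
  lig <- a[lig_sel, , drop = FALSE]

  u <- !duplicated(key(contacts$chain, contacts$res_seq, contacts$i_code))
  roster <- data.frame(res_name = contacts$res_name[u],
                       chain = contacts$chain[u],
                       res_seq = contacts$res_seq[u],
                       i_code = contacts$i_code[u],
                       min_distance = vapply(
                         which(u), function(i) {
                           k <- key(contacts$chain[i], contacts$res_seq[i],
                                    contacts$i_code[i])
                           min(contacts$distance[key(contacts$chain,
                                                     contacts$res_seq,
                                                     contacts$i_code) == k])
                         }, numeric(1)),
                       stringsAsFactors = FALSE)
  roster <- roster[order(roster$chain, roster$res_seq, roster$i_code), ]
  rownames(roster) <- NULL
  rownames(prot) <- rownames(lig) <- NULL

  structure(list(protein = prot, ligand = lig, roster = roster,
                 cutoff = cutoff, ligand_code = ligand,
                 source_id = structure$source_id),
            class = "cluster_geometry")
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf("cluster_geometry (%s / %s, cutoff %.2f A): %d residue(s), %d protein + %d ligand atoms\n",
              x$source_id, x$ligand_code, x$cutoff, nrow(x$roster),
              nrow(x$protein), nrow(x$ligand)))
  cat("residues:", paste(sprintf("%s%d%s", x$roster$res_name, x$roster$res_seq,
                                 x$roster$i_code), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cluster (or any atom set) as XYZ text
#'
#' @param cluster a `cluster_geometry`; protein atoms are written first,
#'   ligand atoms second.
#' @param path optional file path.
#' @param comment comment placed on the second line.
#' @return The XYZ text as a single string (invisibly when written to file).
#' @export
write_xyz <- function(cluster, path = NULL, comment = NULL) {
  atoms <- cluster_atoms(cluster)
  if (nrow(atoms) == 0) stop("cannot write an empty cluster", call. = FALSE)
  if (is.null(comment)) {
    comment <- sprintf("%s %s cluster, cutoff %.2f A",
                       cluster$source_id, cluster$ligand_code, cluster$cutoff)
  }
  lines <- c(as.character(nrow(atoms)), comment,
             sprintf("%-2s %14.6f %14.6f %14.6f",
                     atoms$element, atoms$x, atoms$y, atoms$z))
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

cluster_atoms <- function(cluster) {
  stopifnot(inherits(cluster, "cluster_geometry"))
  rbind(cluster$protein, cluster$ligand)
}

#' Read XYZ text
#'
#' @param text XYZ text (string or lines) or a path to an `.xyz` file.
#' @return data.frame with `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("parse error: XYZ atom-count header is not an integer", call. = FALSE)
  body <- lines[seq(3, length.out = n)]
  tok <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(tok, length, integer(1)) < 4)
  if (length(bad)) stop(sprintf("parse error: malformed XYZ line %d", bad[1] + 2), call. = FALSE)
  data.frame(
    element = vapply(tok, `[`, character(1), 1),
    x = as.numeric(vapply(tok, `[`, character(1), 2)),
    y = as.numeric(vapply(tok, `[`, character(1), 3)),
    z = as.numeric(vapply(tok, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' Settings for a QM-LED input deck
#'
#' Charge and multiplicity are deliberately not defaulted silently: when left
#' `NULL`, [write_qm_input()] falls back to a neutral singlet (0/1) with a
#' prominent warning, since crystal structures carry no protonation
#' information.
#'
#' @param method electronic-structure method keyword (default the
#'   reduced-scaling coupled-cluster method the LED scheme belongs to).
#' @param basis orbital basis set keyword.
#' @param keywords additional keyword-line entries (PNO accuracy etc.).
#' @param charge total charge of the cluster; `NULL` means "unknown".
#' @param mult spin multiplicity; `NULL` means "unknown".
#' @return An object of class `qm_settings`.
#' @export
qm_settings <- function(method = "DLPNO-CCSD(T)", basis = "def2-SVP",
                        keywords = c("NormalPNO", "LED", "TightSCF"),
                        charge = NULL, mult = NULL) {
  structure(list(method = method, basis = basis, keywords = keywords,
                 charge = charge, mult = mult),
            class = "qm_settings")
}

#' Write a two-fragment QM-LED input deck
#'
#' Emits a keyword line declaring the coupled-cluster method with LED, the
#' basis set, an `%mdci LED 2` block, and a coordinate block in which every
#' atom is tagged with its fragment index: protein residues are fragment 1,
#' the ligand is fragment 2.
#'
#' @param cluster a `cluster_geometry`.
#' @param settings a [qm_settings()] object.
#' @param path optional file path.
#' @return The input-deck text as a single string (invisibly when written).
#' @export
write_qm_input <- function(cluster, settings = qm_settings(), path = NULL) {
  stopifnot(inherits(cluster, "cluster_geometry"),
            inherits(settings, "qm_settings"))
  if (nrow(cluster$protein) + nrow(cluster$ligand) == 0) {
    stop("cannot write an empty cluster", call. = FALSE)
  }
  charge <- settings$charge
  mult <- settings$mult
  if (is.null(charge) || is.null(mult)) {
    warning(paste("charge/multiplicity not supplied in qm_settings();",
                  "assuming a neutral singlet (charge 0, multiplicity 1).",
                  "Crystal structures carry no protonation information -",
                  "verify this choice."), call. = FALSE)
    if (is.null(charge)) charge <- 0L
    if (is.null(mult)) mult <- 1L
  }
  frag_line <- function(atoms, frag) {
    sprintf("  %s(%d) %14.6f %14.6f %14.6f", atoms$element, frag,
            atoms$x, atoms$y, atoms$z)
  }
  lines <- c(
    paste("!", settings$method, settings$basis,
          paste(settings$keywords, collapse = " ")),
    "%mdci",
    "  LED 2",
    "end",
    sprintf("* xyz %d %d", charge, mult),
    frag_line(cluster$protein, 1L),
    frag_line(cluster$ligand, 2L),
    "*"
  )
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}
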