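# Calpha-level structure and alignment I/O.
#
# Target residue indexing is 1-based and contiguous 1..L everywhere downstream;
# template PDB numbering is discarded once a template is re-indexed onto the
# target. The alignment dialect is a FASTA MSA whose first record is the
# target (">target <id>") and whose template headers carry key=value fields:
#   >tpl <id> file=<relative pdb path> [chain=<c>] [evalue=<float>]

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")
AA1 <- stats::setNames(names(AA3), AA3)

aa_three_to_one <- function(resid) {
  out <- AA1[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(code) {
  out <- AA3[toupper(code)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Read the Calpha trace of a PDB file
#'
#' @param path PDB file with ATOM records.
#' @param chain optional single chain identifier; by default all chains are
#'   read in file order.
#' @return data.frame with one row per residue having a Calpha atom, columns
#'   \code{index} (residue number), \code{ins} (insertion code, "" if none),
#'   \code{code} (one-letter residue code, non-standard residues map to "X"),
#'   \code{x}, \code{y}, \code{z}. Alternate locations resolve to the first
#'   occurrence; rows are ordered by residue number with insertion codes
#'   preserved in order.
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA"
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no Cα atoms in ", path)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(at$chain, at$resno, ins)
  # two CA records for the same (chain, resno, insert) are alternate
  # locations only if marked as such; otherwise the numbering is corrupt
  dup <- duplicated(key)
  if (any(dup & alt == ""))
    stop("duplicate residue number ", at$resno[dup & alt == ""][1],
         " in ", path)
  first <- !dup  # altloc: first occurrence wins
  at <- at[first, , drop = FALSE]
  ins <- ins[first]
  ord <- order(match(at$chain, unique(at$chain)), at$resno, ins)
  at <- at[ord, , drop = FALSE]
  data.frame(index = at$resno,
             ins = ins[ord],
             code = aa_three_to_one(at$resid),
             x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Write a Calpha model as a PDB file
#'
#' One CA ATOM record per residue, serial numbers sequential, residue numbers
#' taken from the model's target indices. Round-trips through
#' \code{\link{read_pdb_ca}} at format precision (1e-3 Angstrom).
#'
#' @param model a \code{ca_model} (see \code{\link{ca_model}}).
#' @param path output file path.
#' @export
write_pdb_model <- function(model, path) {
  stopifnot(inherits(model, "ca_model"))
  bad <- which(!apply(is.finite(model$xyz), 1, all))
  if (length(bad))
    stop("non-finite coordinates at residue ", model$index[bad[1]])
  n <- nrow(model$xyz)
  codes <- model$codes
  if (is.null(codes)) codes <- rep("X", n)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(model$xyz)),
                   resno = model$index,
                   resid = aa_one_to_three(codes),
                   elety = rep("CA", n),
                   chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Target sequence
#' @param id identifier string.
#' @param residues character vector of one-letter codes (20 standard + "X").
#' @return Object of class \code{spc_target} with fields id, residues, length.
#' @export
spc_target <- function(id, residues) {
  residues <- toupper(as.character(residues))
  ok <- residues %in% names(AA3)
  if (!all(ok)) stop("invalid residue code(s): ",
                     paste(unique(residues[!ok]), collapse = ", "))
  structure(list(id = id, residues = residues, length = length(residues)),
            class = "spc_target")
}

#' Template record
#'
#' A template aligned onto target coordinates: strictly increasing target
#' indices, the template residue codes and Calpha coordinates at those
#' positions.
#'
#' @param id template identifier.
#' @param idx integer target indices (strictly increasing).
#' @param res one-letter residue codes at those positions.
#' @param xyz n x 3 coordinate matrix (may be NULL before structure loading).
#' @param evalue alignment e-value or NA when absent.
#' @param source_path path of the structure file.
#' @param chain optional chain id.
#' @return Object of class \code{spc_template}.
#' @export
spc_template <- function(id, idx, res, xyz = NULL, evalue = NA_real_,
                         source_path = NA_character_, chain = NULL) {
  idx <- as.integer(idx)
  if (length(idx) && any(diff(idx) <= 0L))
    stop("template target indices must be strictly increasing")
  if (!is.null(xyz)) {
    xyz <- as_coord_matrix(xyz)
    stopifnot(nrow(xyz) == length(idx))
  }
  structure(list(id = id, idx = idx, res = as.character(res), xyz = xyz,
                 evalue = as.numeric(evalue), source_path = source_path,
                 chain = chain),
            class = "spc_template")
}

parse_header_fields <- function(header) {
  toks <- strsplit(trimws(header), "\\s+")[[1]]
  kv <- grep("=", toks, fixed = TRUE, value = TRUE)
  fields <- list()
  for (t in kv) {
    p <- strsplit(t, "=", fixed = TRUE)[[1]]
    fields[[p[1]]] <- paste(p[-1], collapse = "=")
  }
  plain <- toks[!grepl("=", toks, fixed = TRUE)]
  list(kind = plain[1], id = if (length(plain) >= 2) plain[2] else NA_character_,
       fields = fields)
}

#' Parse a target--template alignment file
#'
#' Reads the FASTA-MSA alignment dialect: record one is the target
#' (\code{>target <id>}); each template record header is
#' \code{>tpl <id> file=<pdb path> [chain=<c>] [evalue=<float>]}; "-" is the
#' gap character and all sequences have equal aligned length. For each
#' template the mapping covers exactly the columns where both target and
#' template are non-gap; template coordinates are not loaded here (see
#' \code{\link{load_template_structure}}).
#'
#' @param path alignment file.
#' @return List of class \code{spc_alignment} with \code{target}
#'   (\code{spc_target}), \code{templates} (list of \code{spc_template}
#'   without coordinates, plus per-template aligned residue codes) and
#'   \code{dir} (directory of the alignment file, base for relative structure
#'   paths).
#' @export
parse_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_at <- grep("^>", lines)
  if (length(hdr_at) < 2L) stop("alignment needs a target and >= 1 template")
  seqs <- character(length(hdr_at))
  headers <- sub("^>", "", lines[hdr_at])
  bounds <- c(hdr_at, length(lines) + 1L)
  for (k in seq_along(hdr_at)) {
    body <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    seqs[k] <- toupper(gsub("\\s", "", paste(body, collapse = "")))
  }
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences have unequal lengths")
  h1 <- parse_header_fields(headers[1])
  if (!identical(h1$kind, "target"))
    stop("first record must be the target (>target <id>)")
  if (length(h1$fields))
    stop("target record must not carry structure-file fields")
  tgt_cols <- strsplit(seqs[1], "")[[1]]
  tgt_res <- tgt_cols[tgt_cols != "-"]
  target <- spc_target(h1$id, tgt_res)
  tgt_pos <- cumsum(tgt_cols != "-")  # target index per column (0 before first)

  templates <- vector("list", length(headers) - 1L)
  for (k in seq_along(templates)) {
    h <- parse_header_fields(headers[k + 1L])
    if (!identical(h$kind, "tpl"))
      stop("template record ", k, " must start with '>tpl'")
    cols <- strsplit(seqs[k + 1L], "")[[1]]
    both <- cols != "-" & tgt_cols != "-"
    templates[[k]] <- spc_template(
      id = h$id,
      idx = tgt_pos[both],
      res = cols[both],
      evalue = if (is.null(h$fields$evalue)) NA_real_
               else as.numeric(h$fields$evalue),
      source_path = if (is.null(h$fields$file)) NA_character_ else h$fields$file,
      chain = h$fields$chain)
  }
  ids <- vapply(templates, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate template ids")
  structure(list(target = target, templates = templates,
                 dir = dirname(normalizePath(path))),
            class = "spc_alignment")
}

#' Attach template Calpha coordinates from its structure file
#'
#' The k-th aligned (non-gap) template residue is matched to the k-th Calpha
#' residue of the structure file, so the file must contain exactly the
#' template residues present in the alignment.
#'
#' @param template \code{spc_template} from \code{\link{parse_alignment}}.
#' @param base_dir directory against which a relative \code{file=} path is
#'   resolved.
#' @return The template with its \code{xyz} field filled.
#' @export
load_template_structure <- function(template, base_dir = ".") {
  p <- template$source_path
  if (is.na(p)) stop("template ", template$id, " has no structure file")
  if (!file.exists(p)) p <- file.path(base_dir, template$source_path)
  if (!file.exists(p))
    stop("structure file for template ", template$id, " not found: ",
         template$source_path)
  ca <- read_pdb_ca(p, chain = template$chain)
  if (nrow(ca) != length(template$idx))
    stop("template ", template$id, ": alignment has ", length(template$idx),
         " residues but structure has ", nrow(ca), " Cα atoms")
  template$xyz <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(template$xyz) <- NULL
  template
}

#' Trim and re-index a template onto the target
#'
#' Removes residues not mapped to the target (already excluded by the
#' alignment-column walk, so this is idempotent) and validates indexing.
#'
#' @param template \code{spc_template} with coordinates.
#' @param target \code{spc_target}.
#' @return The trimmed, target-indexed template.
#' @export
trim_and_reindex <- function(template, target) {
  keep <- template$idx >= 1L & template$idx <= target$length
  template$idx <- template$idx[keep]
  template$res <- template$res[keep]
  if (!is.null(template$xyz))
    template$xyz <- template$xyz[keep, , drop = FALSE]
  if (length(template$idx) == 0L)
    stop("template ", template$id, " covers no target residue")
  if (!is.null(template$xyz) && !all(is.finite(template$xyz)))
    stop("template ", template$id, " has non-finite coordinates")
  template
}

#' Coverage fraction of a trimmed template
#' @param template trimmed \code{spc_template}.
#' @param target \code{spc_target}.
#' @return covered residues / target length.
#' @export
template_coverage <- function(template, target) {
  length(template$idx) / target$length
}
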