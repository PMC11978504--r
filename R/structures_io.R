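# Structure parsing and artifact writing.
#
# Protein residues populate a `protein_structure` (backbone N/CA/C/O, tokens,
# mask); everything else becomes `context_atoms` minus a configurable
# exclusion list. Altloc handling keeps the highest-occupancy conformer;
# insertion codes are flattened into a strictly increasing per-chain index.

.STANDARD_AA <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
                  "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
                  "THR", "VAL", "TRP", "TYR")

.NUCLEOTIDE_RES <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI",
                     "N", "DN")

.DEFAULT_EXCLUDE <- c("HOH", "NA", "CL", "K", "BR")

#' Construct a protein structure container
#'
#' @param backbone numeric array `[L x 4 x 3]`, atom order N, CA, C, O,
#'   Angstrom. Rows with any missing backbone atom may hold NA.
#' @param residue_index integer `[L]`, strictly increasing within each chain.
#' @param chain_labels integer `[L]`.
#' @param sequence integer tokens `[L]` in `[1, 21]`.
#' @param residue_mask logical `[L]`, TRUE iff all four backbone atoms present.
#' @param chain_ids optional character chain identifiers per residue.
#' @param sidechain_atoms optional data.frame of sidechain atoms
#'   (columns residue, name, x, y, z, element).
#' @param resolution optional numeric, Angstrom.
#' @return an object of class `protein_structure`.
#' @export
protein_structure <- function(backbone, residue_index, chain_labels, sequence,
                              residue_mask, chain_ids = NULL,
                              sidechain_atoms = NULL, resolution = NA_real_) {
  L <- length(sequence)
  stopifnot(identical(dim(backbone), c(L, 4L, 3L)) || identical(dim(backbone), as.integer(c(L, 4, 3))),
            length(residue_index) == L, length(chain_labels) == L,
            length(residue_mask) == L,
            all(sequence >= 1L & sequence <= 21L))
  for (ch in unique(chain_labels)) {
    ri <- residue_index[chain_labels == ch]
    if (length(ri) > 1 && any(diff(ri) <= 0))
      stop("residue_index must be strictly increasing within a chain")
  }
  if (any(!is.finite(backbone[residue_mask, , ])))
    stop("backbone coordinates must be finite where residue_mask is TRUE")
  structure(list(backbone = backbone,
                 residue_index = as.integer(residue_index),
                 chain_labels = as.integer(chain_labels),
                 sequence = as.integer(sequence),
                 residue_mask = as.logical(residue_mask),
                 chain_ids = chain_ids,
                 sidechain_atoms = sidechain_atoms,
                 resolution = resolution),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, %d chain(s), %d masked\n",
              length(x$sequence), length(unique(x$chain_labels)),
              sum(!x$residue_mask)))
  invisible(x)
}

#' Construct a context-atom container
#'
#' @param coords numeric matrix `[n x 3]`, Angstrom.
#' @param element integer atomic numbers (>= 1).
#' @param category character vector in `{small_molecule, nucleotide, metal,
#'   protein_sidechain}`.
#' @return an object of class `context_atoms`.
#' @export
context_atoms <- function(coords = matrix(numeric(0), 0, 3),
                          element = integer(0), category = character(0)) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == length(element), length(element) == length(category),
            all(element >= 1L), all(is.finite(coords)),
            all(category %in% c("small_molecule", "nucleotide", "metal",
                                "protein_sidechain")))
  structure(list(coords = coords, element = as.integer(element),
                 category = category),
            class = "context_atoms")
}

#' @export
print.context_atoms <- function(x, ...) {
  cat(sprintf("context_atoms: %d atoms (%s)\n", length(x$element),
              paste(names(table(x$category)), table(x$category),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

## ---- low-level readers -----------------------------------------------------

.parse_pdb_atoms <- function(lines) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  al <- lines[sel]
  # pad short lines so fixed-column extraction is safe
  al <- formatC(al, width = 80, flag = "-")
  data.frame(
    record = trimws(substr(al, 1, 6)),
    name = substr(al, 13, 16),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resseq = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = substr(al, 27, 27),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element_sym = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE)
}

.parse_pdb_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

.split_cif_row <- function(line) {
  # whitespace split honoring single/double quotes
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

.parse_mmcif_atoms <- function(lines) {
  lines <- trimws(lines, which = "right")
  i <- 1L
  n <- length(lines)
  cols <- character(0)
  rows <- list()
  while (i <= n) {
    if (grepl("^loop_", lines[i])) {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && grepl("^_", trimws(lines[j]))) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1L
      }
      if (length(tags) && all(grepl("^_atom_site\\.", tags))) {
        cols <- sub("^_atom_site\\.", "", tags)
        while (j <= n && !grepl("^(#|loop_|_)", trimws(lines[j])) &&
               nzchar(trimws(lines[j]))) {
          rows[[length(rows) + 1L]] <- .split_cif_row(lines[j])
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("no _atom_site loop found in mmCIF file")
  mat <- do.call(rbind, rows)
  if (ncol(mat) != length(cols)) stop("malformed mmCIF atom_site rows")
  colnames(mat) <- cols
  g <- function(nm, alt = NULL, default = NA) {
    if (nm %in% cols) mat[, nm]
    else if (!is.null(alt) && alt %in% cols) mat[, alt]
    else rep(default, nrow(mat))
  }
  blank_if_dot <- function(v) { v[v %in% c(".", "?")] <- " "; v }
  data.frame(
    record = g("group_PDB", default = "ATOM"),
    name = g("auth_atom_id", "label_atom_id"),
    altloc = blank_if_dot(g("label_alt_id", default = " ")),
    resname = g("auth_comp_id", "label_comp_id"),
    chain = g("auth_asym_id", "label_asym_id"),
    resseq = suppressWarnings(as.integer(g("auth_seq_id", "label_seq_id"))),
    icode = blank_if_dot(g("pdbx_PDB_ins_code", default = " ")),
    x = as.numeric(g("Cartn_x")),
    y = as.numeric(g("Cartn_y")),
    z = as.numeric(g("Cartn_z")),
    occ = suppressWarnings(as.numeric(g("occupancy", default = "1.0"))),
    element_sym = blank_if_dot(g("type_symbol", default = " ")),
    stringsAsFactors = FALSE)
}

# assign atomic numbers; element column wins, then residue-name match for
# monoatomic ions, then atom-name heuristics; unmappable atoms are an error
.assign_elements <- function(at) {
  z <- element_number(at$element_sym)
  miss <- which(is.na(z) | !nzchar(trimws(at$element_sym)))
  for (i in miss) {
    nm <- at$name[i]
    rz <- element_number(at$resname[i])
    two <- toupper(trimws(substr(nm, 1, 2)))
    one <- regmatches(nm, regexpr("[A-Za-z]", nm))
    cand <- NA_integer_
    if (at$record[i] == "HETATM" && !is.na(rz) &&
        sum(at$resname == at$resname[i] & at$resseq == at$resseq[i] &
            at$chain == at$chain[i]) == 1L) {
      cand <- rz                                # monoatomic ion (ZN, FE, ...)
    } else if (nchar(two) == 2 && substr(nm, 1, 1) != " " &&
               !is.na(element_number(two)) &&
               !(two %in% c("CA", "CB", "CG", "CD", "CE", "CZ", "CH",
                            "ND", "NE", "NZ", "NH", "OD", "OE", "OG",
                            "OH", "SD", "SG", "HA", "HB", "HG", "HD",
                            "HE", "HZ", "HH"))) {
      cand <- element_number(two)
    } else if (length(one)) {
      cand <- element_number(one)
    }
    if (is.na(cand))
      stop(sprintf("cannot assign element for atom '%s' in residue %s %s%s",
                   trimws(nm), at$resname[i], at$chain[i], at$resseq[i]))
    z[i] <- cand
  }
  z
}

# altloc resolution: per (chain, resseq, icode, resname, atom name) keep the
# highest-occupancy record, ties broken by the first label encountered
.resolve_altlocs <- function(at) {
  key <- paste(at$chain, at$resseq, at$icode, at$resname, at$name, sep = "\r")
  occ <- ifelse(is.na(at$occ), 1, at$occ)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at2 <- at[ord, , drop = FALSE]
  at2[!duplicated(key[ord]), , drop = FALSE]
}

## ---- assembly --------------------------------------------------------------

.flatten_residue_index <- function(resseq, chain) {
  out <- integer(length(resseq))
  for (ch in unique(chain)) {
    w <- which(chain == ch)
    prev <- NA_integer_
    for (t in seq_along(w)) {
      r <- resseq[w[t]]
      if (is.na(r)) r <- if (is.na(prev)) 1L else prev + 1L
      out[w[t]] <- if (is.na(prev)) r else max(r, prev + 1L)
      prev <- out[w[t]]
    }
  }
  out
}

.assemble_structure <- function(at, exclude) {
  at <- at[!is.na(at$x) & !is.na(at$y) & !is.na(at$z), , drop = FALSE]
  at <- .resolve_altlocs(at)
  at$z_num <- .assign_elements(at)

  rkey <- paste(at$chain, at$resseq, at$icode, at$resname, sep = "\r")
  first <- !duplicated(rkey)
  res <- at[first, c("chain", "resseq", "icode", "resname"), drop = FALSE]
  res$key <- rkey[first]

  has_bb <- vapply(res$key, function(k) {
    nm <- trimws(at$name[rkey == k])
    all(c("N", "CA", "C") %in% nm)
  }, logical(1))
  is_protein <- res$resname %in% .STANDARD_AA | has_bb

  prot <- res[is_protein, , drop = FALSE]
  if (!nrow(prot)) stop("structure contains zero protein residues")
  # order: chain appearance, then file order within chain (already file order)
  L <- nrow(prot)
  backbone <- array(NA_real_, c(L, 4, 3))
  sc_rows <- list()
  for (i in seq_len(L)) {
    sub <- at[rkey == prot$key[i], , drop = FALSE]
    nm <- trimws(sub$name)
    for (a in seq_along(c("N", "CA", "C", "O"))) {
      an <- c("N", "CA", "C", "O")[a]
      w <- which(nm == an)
      if (length(w)) backbone[i, a, ] <- c(sub$x[w[1]], sub$y[w[1]], sub$z[w[1]])
    }
    side <- !(nm %in% c("N", "CA", "C", "O", "OXT")) & sub$z_num != 1L
    if (any(side)) {
      sc_rows[[length(sc_rows) + 1L]] <- data.frame(
        residue = i, name = nm[side], x = sub$x[side], y = sub$y[side],
        z = sub$z[side], element = sub$z_num[side], stringsAsFactors = FALSE)
    }
  }
  sidechain_atoms <- if (length(sc_rows)) do.call(rbind, sc_rows) else NULL
  residue_mask <- apply(backbone, 1, function(m) all(is.finite(m)))
  tokens <- three_to_tokens(prot$resname)
  chains <- factor(prot$chain, levels = unique(prot$chain))
  chain_labels <- as.integer(chains)
  residue_index <- .flatten_residue_index(prot$resseq, prot$chain)

  str <- protein_structure(backbone, residue_index, chain_labels, tokens,
                           residue_mask, chain_ids = as.character(prot$chain),
                           sidechain_atoms = sidechain_atoms)

  # everything that is not a protein residue becomes context, minus exclusions
  het <- at[!(rkey %in% prot$key), , drop = FALSE]
  het <- het[!(het$resname %in% exclude), , drop = FALSE]
  het <- het[het$z_num != 1L, , drop = FALSE]              # drop hydrogens
  if (nrow(het)) {
    hkey <- paste(het$chain, het$resseq, het$icode, het$resname, sep = "\r")
    cat_of <- vapply(seq_len(nrow(het)), function(i) {
      if (het$resname[i] %in% .NUCLEOTIDE_RES) "nucleotide"
      else if (sum(hkey == hkey[i]) == 1L && is_metal_element(het$z_num[i])) "metal"
      else "small_molecule"
    }, character(1))
    ctx <- context_atoms(cbind(het$x, het$y, het$z), het$z_num, cat_of)
  } else {
    ctx <- context_atoms()
  }
  list(structure = str, context = ctx)
}

#' Parse a protein structure plus nonprotein context atoms
#'
#' Standard amino-acid residues (or residues carrying an N/CA/C backbone)
#' populate the protein structure; nonstandard residues get the unknown
#' token. All other residues and atoms become context atoms, except residue
#' names on the exclusion list (waters and common cryo-salts by default) and
#' hydrogens. Categories: nucleotide residue names, monoatomic metal ions,
#' else small molecule. Protein sidechain atoms are retained on the structure
#' and can be promoted to context with [protein_sidechain_context()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param exclude residue names never turned into context atoms.
#' @return list with elements `structure` ([protein_structure]) and
#'   `context` ([context_atoms]).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            exclude = .DEFAULT_EXCLUDE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  at <- if (format == "pdb") .parse_pdb_atoms(lines) else .parse_mmcif_atoms(lines)
  if (!nrow(at)) stop("no atom records parsed from ", path)
  out <- .assemble_structure(at, exclude)
  if (format == "pdb") out$structure$resolution <- .parse_pdb_resolution(lines)
  out
}

#' Promote protein sidechain atoms to context atoms
#'
#' @param structure a [protein_structure] parsed with sidechain atoms.
#' @param residues residue rows to include (default all).
#' @return [context_atoms] of category `protein_sidechain`.
#' @export
protein_sidechain_context <- function(structure, residues = NULL) {
  sc <- structure$sidechain_atoms
  if (is.null(sc) || !nrow(sc)) return(context_atoms())
  if (!is.null(residues)) sc <- sc[sc$residue %in% residues, , drop = FALSE]
  if (!nrow(sc)) return(context_atoms())
  context_atoms(cbind(sc$x, sc$y, sc$z), sc$element,
                rep("protein_sidechain", nrow(sc)))
}

#' Concatenate context-atom sets
#' @param ... [context_atoms] objects.
#' @return a single [context_atoms].
#' @export
concat_context <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, function(x) length(x$element) > 0, logical(1))]
  if (!length(xs)) return(context_atoms())
  context_atoms(do.call(rbind, lapply(xs, `[[`, "coords")),
                unlist(lapply(xs, `[[`, "element")),
                unlist(lapply(xs, `[[`, "category")))
}

## ---- writers ---------------------------------------------------------------

.pdb_atom_line <- function(serial, name, resname, chain, resseq, xyz, element,
                           het = FALSE) {
  nm <- if (nchar(name) < 4 && nchar(element) == 1) sprintf(" %-3s", name)
        else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial %% 100000, nm, " ",
          resname, substr(chain, 1, 1), resseq %% 10000, " ",
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, toupper(element))
}

#' Write a structure (optionally with packed sidechains and context) as PDB
#'
#' Glycine rows emit no sidechain atoms; rows of `sidechain_coords` follow the
#' per-residue 14-atom naming convention of [atom14_names()].
#'
#' @param structure a [protein_structure].
#' @param sidechain_coords optional numeric array `[L x 14 x 3]` (slots 5+ are
#'   sidechain atoms; NA slots are skipped). When NULL, any parsed sidechain
#'   atoms on the structure are not emitted.
#' @param path output path.
#' @param context optional [context_atoms] written as HETATM records.
#' @return invisible `path`.
#' @export
write_structure <- function(structure, sidechain_coords = NULL, path,
                            context = NULL) {
  L <- length(structure$sequence)
  if (!is.null(sidechain_coords) &&
      !identical(dim(sidechain_coords)[1], L))
    stop("sidechain_coords length does not match the structure")
  chains <- structure$chain_ids
  if (is.null(chains)) chains <- LETTERS[structure$chain_labels]
  lines <- character(0)
  serial <- 0L
  bbn <- c("N", "CA", "C", "O")
  for (i in seq_len(L)) {
    resname <- tokens_to_three(structure$sequence[i])
    nm14 <- atom14_names(structure$sequence[i])
    for (a in 1:4) {
      xyz <- structure$backbone[i, a, ]
      if (all(is.finite(xyz))) {
        serial <- serial + 1L
        lines <- c(lines, .pdb_atom_line(serial, bbn[a], resname, chains[i],
                                         structure$residue_index[i], xyz,
                                         substr(bbn[a], 1, 1)))
      }
    }
    if (!is.null(sidechain_coords)) {
      for (a in 5:14) {
        if (a > length(nm14) || !nzchar(nm14[a])) next
        xyz <- sidechain_coords[i, a, ]
        if (all(is.finite(xyz))) {
          serial <- serial + 1L
          el <- substr(gsub("[0-9]", "", nm14[a]), 1, 1)
          lines <- c(lines, .pdb_atom_line(serial, nm14[a], resname, chains[i],
                                           structure$residue_index[i], xyz, el))
        }
      }
    }
  }
  if (!is.null(context) && length(context$element)) {
    for (j in seq_along(context$element)) {
      serial <- serial + 1L
      el <- toupper(element_symbol(context$element[j]))
      resname <- if (context$category[j] == "metal") substr(el, 1, 3) else "LIG"
      lines <- c(lines, .pdb_atom_line(serial, el, resname, "X", j,
                                       context$coords[j, ], el, het = TRUE))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write designed sequences as FASTA
#'
#' One record per design; headers carry the design id, confidence and
#' sampling temperature.
#'
#' @param designs list of `design_result` objects (from [sample_sequence()]),
#'   or a character vector of sequences.
#' @param path output path.
#' @return invisible `path`.
#' @export
write_fasta <- function(designs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.character(designs)) designs <- lapply(designs, function(s) list(sequence_string = s))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    seqstr <- if (!is.null(d$sequence_string)) d$sequence_string
              else paste(tokens_to_one(d$sequence), collapse = "")
    conf <- if (!is.null(d$confidence)) sprintf(" confidence=%.2f", d$confidence) else ""
    temp <- if (!is.null(d$temperature)) sprintf(" T=%.3f", d$temperature) else ""
    id <- if (!is.null(d$id)) d$id else sprintf("design_%d", i)
    writeLines(sprintf(">%s%s%s", id, conf, temp), con)
    writeLines(seqstr, con)
  }
  invisible(path)
}

#' Read a FASTA file
#' @param path input path.
#' @return named character vector of sequences (names are full headers).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

#' Write a JSON sidecar with per-position probabilities and scores
#'
#' @param designs list of `design_result` objects.
#' @param path output path.
#' @return invisible `path`.
#' @export
write_design_json <- function(designs, path) {
  payload <- lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    list(id = if (!is.null(d$id)) d$id else sprintf("design_%d", i),
         sequence = paste(tokens_to_one(d$sequence), collapse = ""),
         confidence = d$confidence,
         temperature = d$temperature,
         decoding_order = d$decoding_order,
         log_probs = d$log_probs)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
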