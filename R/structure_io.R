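#' @importFrom stats sd setNames rnorm runif optimize uniroot approx splinefun
#' @importFrom utils write.table read.table head tail
NULL

# three-letter codes accepted as protein residues
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Van der Waals radius table
#'
#' Chothia-style united-atom radii used for solvent-accessible surface
#' area calculations: C 1.87, N 1.50, O 1.40, S 1.85 Angstrom.  Elements
#' not listed fall back to the `.default` entry.  Radii are assigned at
#' read time, never taken from the coordinate file.
#'
#' @param file optional JSON file with named element -> radius overrides.
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(file = NULL) {
  r <- c(C = 1.87, N = 1.50, O = 1.40, S = 1.85, H = 1.00, P = 1.80,
         .default = 1.80)
  if (!is.null(file)) {
    ov <- unlist(jsonlite::read_json(file))
    r[names(ov)] <- as.numeric(ov)
  }
  r
}

.assign_radii <- function(element, radii = vdw_radii()) {
  out <- radii[element]
  out[is.na(out)] <- radii[[".default"]]
  unname(out)
}

#' Construct a fibril model
#'
#' A `fibril_model` is the container all geometry and energy operations
#' act on: a flat atom table plus (optionally) a layer ordering and the
#' helical parameters of the stack.  Layers are chains; a fibril layer is
#' one protein chain of the stacked model.
#'
#' @param atoms data.frame with columns `chain`, `resid` (author residue
#'   numbering), `resname` (3-letter), `atom_name`, `element`, `x`, `y`,
#'   `z`, and logical `hydrogen` and `het`.  A `vdw` column is added if
#'   absent.
#' @param label polymorph name, e.g. `"Sc4"`.
#' @param helical optional [helical_params()].
#' @param layers optional character vector of chain ids ordered along the
#'   fibril axis (set by [order_layers()]).
#' @param central index into `layers` of the central layer.
#' @param radii radius table used to fill the `vdw` column.
#' @return an object of class `fibril_model`.
#' @export
fibril_model <- function(atoms, label = "", helical = NULL, layers = NULL,
                         central = NA_integer_, radii = vdw_radii()) {
  need <- c("chain", "resid", "resname", "atom_name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (is.null(atoms$hydrogen))
    atoms$hydrogen <- atoms$element == "H"
  if (is.null(atoms$het))
    atoms$het <- !(atoms$resname %in% .aa3)
  if (is.null(atoms$vdw))
    atoms$vdw <- .assign_radii(atoms$element, radii)
  if (any(atoms$vdw <= 0)) stop("vdw radii must be positive")
  pr_chains <- unique(atoms$chain[!atoms$het])
  if (length(pr_chains) == 0L) stop("empty model: no protein atoms")
  if (!is.null(layers)) {
    if (!setequal(layers, pr_chains))
      stop("layers must be a permutation of the protein chain ids")
  }
  structure(list(atoms = atoms, label = label, helical = helical,
                 layers = layers, central = central),
            class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  a <- x$atoms[!x$atoms$het, ]
  cat("fibril_model", if (nzchar(x$label)) sprintf("'%s'", x$label), "\n")
  cat(sprintf("  %d protein atoms, %d chains, %d residues\n",
              nrow(a), length(unique(a$chain)),
              nrow(unique(a[, c("chain", "resid")]))))
  if (!is.null(x$layers))
    cat("  layers:", paste(x$layers, collapse = " "),
        sprintf("(central: %s)", x$layers[x$central]), "\n")
  if (!is.null(x$helical))
    cat(sprintf("  helical: rise %.3f A, twist %.3f deg (%s)\n",
                x$helical$rise, x$helical$twist, x$helical$handedness))
  invisible(x)
}

.protein_atoms <- function(model, heavy = TRUE) {
  a <- model$atoms[!model$atoms$het, ]
  if (heavy) a <- a[!a$hydrogen, ]
  a
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Read a fibril atomic model
#'
#' Loads an mmCIF or PDB coordinate file into a [fibril_model()].  Author
#' residue numbering is kept (it is the numbering the field quotes core
#' spans in).  Waters and other heteroatoms are dropped unless
#' `include_het = TRUE`; for atoms with alternate locations only the
#' highest-occupancy conformer is kept; insertion codes are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @param include_het keep non-water heteroatoms.
#' @param label polymorph label stored on the model; defaults to the
#'   file base name.
#' @param radii vdW radius table, see [vdw_radii()].
#' @return a `fibril_model`.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           include_het = FALSE, label = NULL,
                           radii = vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- tryCatch(
    if (format == "mmcif") .read_mmcif_atoms(path)
    else bio3d::read.pdb(path, verbose = FALSE)$atom,
    error = function(e) stop("could not parse '", path, "' as ", format,
                             ": ", conditionMessage(e)))
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert)))
    stop("insertion codes are not supported in fibril models")
  # highest-occupancy altloc per atom site
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), ]
  }
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | !nzchar(elem)
  if (any(bad))  # fall back to first letter of the atom name
    elem[bad] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[bad])), 1, 1)
  atoms <- data.frame(chain = as.character(at$chain),
                      resid = as.integer(at$resno),
                      resname = trimws(at$resid),
                      atom_name = trimws(at$elety),
                      element = elem,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  atoms$het <- !(atoms$resname %in% .aa3)
  atoms <- atoms[atoms$resname != "HOH", ]
  if (!include_het) atoms <- atoms[!atoms$het, ]
  if (nrow(atoms) == 0L || all(atoms$het))
    stop("empty model: no protein atoms in ", path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  fibril_model(atoms, label = label, radii = radii)
}

#' Write a fibril model to mmCIF or PDB
#'
#' @param model a `fibril_model`.
#' @param path output file; format chosen by extension unless given.
#' @param format `"auto"`, `"mmcif"` or `"pdb"`.
#' @export
write_structure <- function(model, path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    n <- nrow(a)
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(.coords(a))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resid, resid = a$resname,
                     chain = a$chain, elety = a$atom_name,
                     elesy = a$element, o = rep(1, n), b = rep(0, n))
  } else {
    .write_mmcif(a, path, label = model$label)
  }
  invisible(path)
}

# generic _atom_site loop parser: tolerates any column order, prefers
# auth_* (author) numbering, returns a data.frame shaped like
# bio3d::read.pdb()$atom for the columns read_structure uses
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_i <- grep("^_atom_site\\.", lines)
  if (length(tag_i) == 0L) stop("no _atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_i]))
  start <- max(tag_i) + 1L
  rows <- character()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(#|_|loop_|data_)", ln)) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0L) stop("empty _atom_site loop")
  fields <- strsplit(rows, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop("malformed _atom_site row (expected ", length(tags), " fields)")
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  clean <- function(v) ifelse(v %in% c(".", "?"), NA_character_, v)
  data.frame(
    type = pick("group_PDB"),
    elety = clean(pick("auth_atom_id", "label_atom_id")),
    alt = clean(pick("label_alt_id")),
    resid = clean(pick("auth_comp_id", "label_comp_id")),
    chain = clean(pick("auth_asym_id", "label_asym_id")),
    resno = as.integer(clean(pick("auth_seq_id", "label_seq_id"))),
    insert = clean(pick("pdbx_PDB_ins_code")),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    o = suppressWarnings(as.numeric(clean(pick("occupancy")))),
    elesy = clean(pick("type_symbol")),
    stringsAsFactors = FALSE)
}

# minimal atom_site mmCIF writer (the dialect read_structure consumes)
.write_mmcif <- function(a, path, label = "model") {
  id <- gsub("[^A-Za-z0-9_-]", "_", ifelse(nzchar(label), label, "model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", id), "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.label_asym_id",
               "_atom_site.label_seq_id",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "%-6s %-6d %-2s %-4s %-3s %-2s %-5d %8.3f %8.3f %8.3f %.2f %.2f %-5d %-3s %-2s %-4s 1",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
    a$atom_name, a$resname, a$chain, a$resid,
    a$x, a$y, a$z, 1, 0, a$resid, a$resname, a$chain, a$atom_name)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}

#' Order fibril layers along the axis
#'
#' Sorts the model's chains by the projection of their C-alpha centroids
#' onto the fibril axis and records the central layer (for an even stack
#' the lower of the two middle layers is taken).  Chains with
#' non-identical residue-number sets trigger a heterogeneity warning,
#' not an error.
#'
#' @param model a `fibril_model`.
#' @param axis a [fibril_axis()]; estimated with [estimate_axis()] when
#'   `NULL`.
#' @return the model with `layers` and `central` set.
#' @export
order_layers <- function(model, axis = NULL) {
  a <- .protein_atoms(model)
  chains <- unique(a$chain)
  if (length(chains) < 1L) stop("no protein chains")
  rs <- lapply(split(a$resid, a$chain), unique)
  if (length(chains) > 1L &&
      !all(vapply(rs, function(r) setequal(r, rs[[1]]), logical(1))))
    warning("chains have non-identical residue sets (mixed entities)")
  if (is.null(axis)) axis <- estimate_axis(model)
  cent <- .chain_centroids(a, chains)
  proj <- as.numeric(cent %*% axis$direction)
  ord <- order(proj)
  model$layers <- chains[ord]
  model$central <- ceiling(length(chains) / 2)
  model
}

.chain_centroids <- function(a, chains) {
  ca <- a[a$atom_name == "CA", ]
  use <- if (nrow(ca) >= length(chains)) ca else a
  t(vapply(chains, function(ch) colMeans(.coords(use[use$chain == ch, ])),
           numeric(3)))
}

#' Residue span
#'
#' An inclusive run of residue indices, e.g. the printed core span
#' Y69-Q132 is `residue_span(69, 132)`.
#'
#' @param first,last first and last residue index (inclusive).
#' @param label optional text label.
#' @export
residue_span <- function(first, last, label = "") {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first > last)
    stop("invalid span: first must be <= last")
  structure(list(first = first, last = last, label = label),
            class = "residue_span")
}

#' @export
print.residue_span <- function(x, ...) {
  cat(sprintf("residue_span %d-%d (%d residues)%s\n", x$first, x$last,
              x$last - x$first + 1L,
              if (nzchar(x$label)) paste0(" ", x$label) else ""))
  invisible(x)
}

.as_span_list <- function(spans) {
  if (inherits(spans, "residue_span")) list(spans) else spans
}

#' Ordered-core spans of a chain
#'
#' Maximal runs of consecutive residue indices present in the model for
#' one chain, sorted ascending: the machine-readable version of printed
#' core statements such as "S4-Y35" plus "Q47-S53".
#'
#' @param model a `fibril_model`.
#' @param chain chain id.
#' @return list of [residue_span()].
#' @export
ordered_spans <- function(model, chain) {
  a <- .protein_atoms(model, heavy = FALSE)
  r <- sort(unique(a$resid[a$chain == chain]))
  if (length(r) == 0L) stop("chain not found: ", chain)
  brk <- c(0L, which(diff(r) > 1L), length(r))
  lapply(seq_len(length(brk) - 1L), function(i)
    residue_span(r[brk[i] + 1L], r[brk[i + 1L]]))
}

#' Count residues covered by spans
#'
#' Sum of inclusive span lengths; spans must not overlap.
#'
#' @param spans list of [residue_span()] (a single span is accepted).
#' @return integer residue count.
#' @export
count_span_residues <- function(spans) {
  spans <- .as_span_list(spans)
  if (length(spans) == 0L) return(0L)
  m <- t(vapply(spans, function(s) c(s$first, s$last), integer(2)))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2]))
    stop("overlapping spans")
  sum(m[, 2] - m[, 1] + 1L)
}

#' Chain/span report
#'
#' One row per ordered span per chain: chain, first, last, n_residues.
#'
#' @param model a `fibril_model`.
#' @return data.frame.
#' @export
chain_span_report <- function(model) {
  chains <- unique(.protein_atoms(model)$chain)
  do.call(rbind, lapply(chains, function(ch) {
    sp <- ordered_spans(model, ch)
    data.frame(chain = ch,
               first = vapply(sp, `[[`, integer(1), "first"),
               last = vapply(sp, `[[`, integer(1), "last"),
               n_residues = vapply(sp, function(s)
                 s$last - s$first + 1L, integer(1)))
  }))
}
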