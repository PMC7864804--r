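#' Read an atomic model from PDB or mmCIF
#'
#' Parses ATOM/HETATM records from a PDB file or the `_atom_site` loop of
#' an mmCIF file (format chosen by extension, or by sniffing the content
#' when the extension is ambiguous). Alternate locations are resolved by
#' keeping the highest-occupancy conformer (ties: first encountered);
#' insertion codes are preserved as part of the residue identity.
#'
#' @param path file path
#' @return an [em_model()]
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_emvalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
    any(grepl("^_atom_site\\.", lines))
  atoms <- if (is_cif) parse_mmcif(lines) else parse_pdb(lines)
  if (!nrow(atoms)) stop_emvalid("no atom records in %s", path)
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  em_model(atoms)
}

parse_pdb <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) return(data.frame())
  fx <- function(a, b) substr(rec, a, b)
  xyz <- suppressWarnings(cbind(as.numeric(fx(31, 38)),
                                as.numeric(fx(39, 46)),
                                as.numeric(fx(47, 54))))
  if (anyNA(xyz)) stop_emvalid("unparsable coordinate field in PDB record")
  occ <- suppressWarnings(as.numeric(fx(55, 60))); occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(fx(61, 66))); b[is.na(b)] <- 0
  el <- trimws(fx(77, 78))
  nm <- trimws(fx(13, 16))
  el[el == ""] <- guess_element(nm[el == ""])
  data.frame(
    chain = trimws(fx(22, 22)), resno = as.integer(trimws(fx(23, 26))),
    ins = trimws(fx(27, 27)), resid = trimws(fx(18, 20)),
    atom = nm, alt = trimws(fx(17, 17)), element = el,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = occ, b = b,
    stringsAsFactors = FALSE)
}

## Pragmatic mmCIF subset: a single _atom_site loop with whitespace-
## delimited rows; quoted tokens handled minimally.
parse_mmcif <- function(lines) {
  hdr_i <- grep("^_atom_site\\.", lines)
  if (!length(hdr_i)) return(data.frame())
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_i]))
  body <- lines[(max(hdr_i) + 1):length(lines)]
  end <- which(startsWith(body, "#") | startsWith(body, "loop_") |
                 startsWith(body, "_"))
  if (length(end)) body <- body[seq_len(min(end) - 1)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(data.frame())
  toks <- lapply(body, cif_tokens)
  nf <- length(fields)
  ok <- vapply(toks, length, 1L) == nf
  tab <- as.data.frame(do.call(rbind, toks[ok]), stringsAsFactors = FALSE)
  names(tab) <- fields
  get <- function(...) {
    for (f in c(...)) if (!is.null(tab[[f]])) return(tab[[f]])
    rep(NA_character_, nrow(tab))
  }
  num <- function(v, def) { x <- suppressWarnings(as.numeric(v)); x[is.na(x)] <- def; x }
  blank <- function(v) { v[v %in% c(".", "?") | is.na(v)] <- ""; v }
  xyz <- suppressWarnings(cbind(as.numeric(get("Cartn_x")),
                                as.numeric(get("Cartn_y")),
                                as.numeric(get("Cartn_z"))))
  if (anyNA(xyz)) stop_emvalid("unparsable coordinate field in mmCIF _atom_site loop")
  data.frame(
    chain = blank(get("auth_asym_id", "label_asym_id")),
    resno = as.integer(num(get("auth_seq_id", "label_seq_id"), NA)),
    ins = blank(get("pdbx_PDB_ins_code")),
    resid = blank(get("auth_comp_id", "label_comp_id")),
    atom = blank(get("auth_atom_id", "label_atom_id")),
    alt = blank(get("label_alt_id")),
    element = blank(get("type_symbol")),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = num(get("occupancy"), 1), b = num(get("B_iso_or_equiv"), 0),
    stringsAsFactors = FALSE)
}

cif_tokens <- function(line) {
  out <- character(); s <- trimws(line)
  while (nzchar(s)) {
    if (substr(s, 1, 1) %in% c("'", "\"")) {
      q <- substr(s, 1, 1)
      close <- regexpr(paste0(q, "( |$)"), substring(s, 2))
      tok <- substr(s, 2, close); s <- trimws(substring(s, close + 2))
      out <- c(out, tok)
    } else {
      sp <- regexpr("[ \t]", s)
      if (sp == -1) { out <- c(out, s); s <- "" }
      else { out <- c(out, substr(s, 1, sp - 1)); s <- trimws(substring(s, sp)) }
    }
  }
  out
}

## Keep highest-occupancy alternate conformer per atom (ties: first).
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "|")
  keep <- unlist(lapply(split(seq_along(key), factor(key, levels = unique(key))),
                        function(i) i[which.max(atoms$occ[i])]), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write an atomic model as PDB
#'
#' @param model an [em_model()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  pad_name <- function(nm, el) {
    ## PDB convention: element right-justified in cols 13-14
    ifelse(nchar(el) == 1 & nchar(nm) < 4, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  }
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, pad_name(a$atom, a$element), a$resid,
    substr(a$chain, 1, 1), a$resno, a$ins, a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
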