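#' Partitioned morphological character matrices
#'
#' A `char_matrix` holds a taxa-by-characters grid of discrete states
#' (alphabet 0--9) together with the taphonomic partition of every
#' character into biomineralized ("hard") and non-biomineralized ("soft")
#' tissue types, and the name of the outgroup taxon used to root all trees.
#'
#' Cells are stored as integer bitmasks: bit `s` set means state `s` was
#' observed, so a polymorphic cell \{0,1\} is `3L`. `NA` encodes MISSING
#' ("?"); inapplicable codings ("-") are collapsed to MISSING on input,
#' since the deletion protocol codes taphonomic absence as uncertainty
#' rather than as a state.
#'
#' @param cells integer matrix (taxa x characters) of state bitmasks with
#'   `NA` for missing entries; rownames are taxon labels.
#' @param partition character vector, one of `"hard"`/`"soft"` per character.
#' @param outgroup single taxon label; trees are rooted on this terminal.
#' @param ordering optional per-character `"unordered"`/`"ordered"` flag
#'   (default all unordered).
#' @return an object of class `char_matrix`.
#' @export
character_matrix <- function(cells, partition, outgroup, ordering = NULL) {
  if (!is.matrix(cells) || !is.integer(cells))
    stop("`cells` must be an integer matrix of state bitmasks")
  taxa <- rownames(cells)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("`cells` must have taxon labels as rownames")
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  nc <- ncol(cells)
  if (nrow(cells) < 1L)
    stop("matrix must contain at least one taxon")
  if (nc < 1L)
    stop("matrix must contain at least one character")
  partition <- as.character(partition)
  if (length(partition) != nc)
    stop("partition labels ", length(partition), " characters but matrix has ", nc)
  if (!all(partition %in% c("hard", "soft")))
    stop("partition labels must be 'hard' or 'soft'")
  if (length(outgroup) != 1L || !outgroup %in% taxa)
    stop("outgroup must name one taxon in the matrix")
  if (is.null(ordering)) ordering <- rep("unordered", nc)
  if (length(ordering) != nc || !all(ordering %in% c("unordered", "ordered")))
    stop("ordering must be 'unordered'/'ordered' per character")
  bad <- which(!is.na(cells) & (cells <= 0L | cells > 1023L))
  if (length(bad))
    stop("cell state-sets must be non-empty subsets of states 0-9 (cell ",
         bad[1L], " invalid)")
  structure(
    list(cells = cells, partition = partition, outgroup = outgroup,
         ordering = ordering),
    class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf(
    "char_matrix: %d taxa x %d characters (%d hard, %d soft), outgroup '%s'\n",
    nrow(x$cells), ncol(x$cells), sum(x$partition == "hard"),
    sum(x$partition == "soft"), x$outgroup))
  cat(sprintf("missing: %.1f%% overall (hard %.1f%%, soft %.1f%%)\n",
              100 * mean(is.na(x$cells)),
              100 * missing_fraction(x, "hard"),
              100 * missing_fraction(x, "soft")))
  invisible(x)
}

n_taxa <- function(m) nrow(m$cells)
n_char <- function(m) ncol(m$cells)
taxa_of <- function(m) rownames(m$cells)

#' Fraction of missing cells, overall or per partition
#'
#' @param m a `char_matrix`.
#' @param which `"all"`, `"hard"` or `"soft"`.
#' @return fraction in \[0, 1\]; `NaN` when the partition is empty.
#' @export
missing_fraction <- function(m, which = "all") {
  cols <- if (which == "all") seq_len(ncol(m$cells)) else which(m$partition == which)
  mean(is.na(m$cells[, cols, drop = FALSE]))
}

state_bits <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:9)) != 0L) - 1L

states_to_mask <- function(states) {
  as.integer(sum(bitwShiftL(1L, unique(states))))
}

#' Character-state strings of a matrix
#'
#' Renders cells as compact strings: single states as digits, polymorphic
#' sets as digit runs (e.g. `"01"`), MISSING as `"?"`.
#'
#' @param m a `char_matrix`.
#' @return character matrix with the same dimnames as the cell grid.
#' @export
state_strings <- function(m) {
  out <- matrix("?", nrow(m$cells), ncol(m$cells), dimnames = dimnames(m$cells))
  idx <- which(!is.na(m$cells))
  out[idx] <- vapply(m$cells[idx],
                     function(v) paste(state_bits(v), collapse = ""), "")
  out
}

cell_token <- function(mask, poly_open = "{", poly_close = "}") {
  if (is.na(mask)) return("?")
  s <- state_bits(mask)
  if (length(s) == 1L) as.character(s)
  else paste0(poly_open, paste(s, collapse = ""), poly_close)
}

# --- sequence tokenization shared by both dialects ------------------------

parse_state_row <- function(seq, line_no, file) {
  chars <- strsplit(seq, "")[[1L]]
  out <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("?", "-")) { out <- c(out, NA_integer_); i <- i + 1L; next }
    if (ch %in% c("{", "[", "(")) {
      close <- c("{" = "}", "[" = "]", "(" = ")")[[ch]]
      j <- i + 1L
      states <- integer(0)
      while (j <= length(chars) && chars[j] != close) {
        if (!grepl("[0-9]", chars[j]))
          stop("parse error in '", file, "' line ", line_no,
               ": invalid state '", chars[j], "' in polymorphic set")
        states <- c(states, as.integer(chars[j]))
        j <- j + 1L
      }
      if (j > length(chars))
        stop("parse error in '", file, "' line ", line_no,
             ": unterminated polymorphic set")
      if (length(states) < 1L)
        stop("parse error in '", file, "' line ", line_no,
             ": empty polymorphic set")
      out <- c(out, states_to_mask(states))
      i <- j + 1L
      next
    }
    if (grepl("[0-9]", ch)) {
      out <- c(out, states_to_mask(as.integer(ch)))
      i <- i + 1L
      next
    }
    stop("parse error in '", file, "' line ", line_no,
         ": unexpected character '", ch, "'")
  }
  out
}

# --- partition sidecar ----------------------------------------------------

#' Read a hard/soft partition sidecar file
#'
#' The sidecar is a CSV with columns `char_index` (1-based) and `label`
#' (`hard`/`soft`), optionally `ordering` (`unordered`/`ordered`).
#'
#' @param path CSV file path.
#' @param n_char expected character count (validated).
#' @return list with `partition` and `ordering` vectors.
#' @export
read_partition <- function(path, n_char) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("char_index", "label") %in% names(df)))
    stop("partition file must have columns char_index,label")
  if (nrow(df) != n_char)
    stop("partition file lists ", nrow(df), " labels for a ", n_char,
         "-character matrix")
  if (!setequal(df$char_index, seq_len(n_char)))
    stop("partition file char_index must cover 1..", n_char)
  df <- df[order(df$char_index), ]
  ordering <- if ("ordering" %in% names(df)) df$ordering else rep("unordered", n_char)
  list(partition = tolower(df$label), ordering = ordering)
}

#' Write a hard/soft partition sidecar file
#' @param m a `char_matrix`.
#' @param path output CSV path.
#' @export
write_partition <- function(m, path) {
  df <- data.frame(char_index = seq_len(ncol(m$cells)),
                   label = m$partition, ordering = m$ordering)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- NEXUS ----------------------------------------------------------------

read_nexus_cells <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- gsub("\\[[^]]*\\]", "", lines) # nexus comments, not poly sets
  # dimensions
  dim_line <- grep("DIMENSIONS", stripped, ignore.case = TRUE)[1L]
  if (is.na(dim_line))
    stop("parse error in '", path, "': no DIMENSIONS statement")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", stripped[dim_line],
                         ignore.case = TRUE))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", stripped[dim_line],
                         ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchr))
    stop("parse error in '", path, "' line ", dim_line,
         ": cannot read NTAX/NCHAR")
  mat_line <- grep("^\\s*MATRIX\\s*$", stripped, ignore.case = TRUE)[1L]
  if (is.na(mat_line))
    stop("parse error in '", path, "': no MATRIX block")
  rows <- list()
  order_seen <- character(0)
  i <- mat_line + 1L
  while (i <= length(stripped)) {
    ln <- trimws(stripped[i])
    if (ln == ";" || grepl(";\\s*$", ln)) {
      ln <- sub(";\\s*$", "", ln)
      if (nzchar(trimws(ln))) {
        i_parsed <- parse_matrix_line(ln, i, path)
        rows[[i_parsed$taxon]] <- c(rows[[i_parsed$taxon]], i_parsed$states)
        if (!i_parsed$taxon %in% order_seen)
          order_seen <- c(order_seen, i_parsed$taxon)
      }
      break
    }
    if (nzchar(ln)) {
      p <- parse_matrix_line(ln, i, path)
      rows[[p$taxon]] <- c(rows[[p$taxon]], p$states)
      if (!p$taxon %in% order_seen) order_seen <- c(order_seen, p$taxon)
    }
    i <- i + 1L
  }
  build_cells(rows, order_seen, ntax, nchr, path)
}

parse_matrix_line <- function(ln, line_no, path) {
  m <- regmatches(ln, regexec("^('[^']+'|\\S+)\\s+(.*)$", ln))[[1L]]
  if (length(m) < 3L)
    stop("parse error in '", path, "' line ", line_no, ": expected taxon and states")
  taxon <- gsub("^'|'$", "", m[2L])
  list(taxon = taxon, states = parse_state_row(m[3L], line_no, path))
}

build_cells <- function(rows, order_seen, ntax, nchr, path) {
  if (length(rows) != ntax)
    stop("'", path, "': header declares ", ntax, " taxa but ", length(rows),
         " parsed")
  lens <- vapply(rows, length, 0L)
  if (any(lens != nchr))
    stop("'", path, "': taxon '", names(rows)[lens != nchr][1L], "' has ",
         lens[lens != nchr][1L], " characters, header declares ", nchr)
  cells <- do.call(rbind, rows[order_seen])
  rownames(cells) <- order_seen
  storage.mode(cells) <- "integer"
  cells
}

write_nexus_cells <- function(m, path) {
  ss <- m$cells
  tok <- apply(ss, c(1, 2), cell_token)
  rows <- apply(tok, 1L, paste, collapse = "")
  labels <- rownames(m$cells)
  quoted <- ifelse(grepl("[^A-Za-z0-9_.]", labels), paste0("'", labels, "'"), labels)
  pad <- formatC(quoted, width = max(nchar(quoted)), flag = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(ss), ncol(ss)),
    "  FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
    "  MATRIX",
    paste0("    ", pad, " ", rows),
    "  ;",
    "END;"), con)
  invisible(path)
}

# --- TNT ------------------------------------------------------------------

read_tnt_cells <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- gsub("'[^']*'", "", lines)
  xl <- grep("^\\s*xread", stripped, ignore.case = TRUE)[1L]
  if (is.na(xl))
    stop("parse error in '", path, "': no xread block")
  # first line after xread holding two integers: nchar ntax
  i <- xl
  dims <- NULL
  while (i <= length(stripped)) {
    tk <- regmatches(stripped[i], regexec("(\\d+)\\s+(\\d+)", stripped[i]))[[1L]]
    if (length(tk) == 3L) { dims <- as.integer(tk[2:3]); break }
    i <- i + 1L
  }
  if (is.null(dims))
    stop("parse error in '", path, "': no dimensions after xread")
  nchr <- dims[1L]; ntax <- dims[2L]
  rows <- list(); order_seen <- character(0)
  i <- i + 1L
  while (i <= length(stripped)) {
    ln <- trimws(stripped[i])
    hit_end <- grepl(";\\s*$", ln)
    ln <- sub(";\\s*$", "", ln)
    if (nzchar(ln)) {
      p <- parse_matrix_line(ln, i, path)
      rows[[p$taxon]] <- c(rows[[p$taxon]], p$states)
      if (!p$taxon %in% order_seen) order_seen <- c(order_seen, p$taxon)
    }
    if (hit_end) break
    i <- i + 1L
  }
  build_cells(rows, order_seen, ntax, nchr, path)
}

write_tnt_cells <- function(m, path) {
  tok <- apply(m$cells, c(1, 2), cell_token, poly_open = "[", poly_close = "]")
  rows <- apply(tok, 1L, paste, collapse = "")
  labels <- rownames(m$cells)
  quoted <- ifelse(grepl("[^A-Za-z0-9_.]", labels), paste0("'", labels, "'"), labels)
  pad <- formatC(quoted, width = max(nchar(quoted)), flag = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "xread",
    sprintf("%d %d", ncol(m$cells), nrow(m$cells)),
    paste0(pad, " ", rows),
    ";"), con)
  invisible(path)
}

# --- public IO ------------------------------------------------------------

#' Read a partitioned character matrix
#'
#' Parses a NEXUS `DATA`/`CHARACTERS` matrix block or a TNT `xread` block
#' (simple and interleaved layouts, `?` missing, `-` inapplicable mapped to
#' missing, polymorphic sets in `{}`, `[]` or `()`), attaches the hard/soft
#' partition from a sidecar CSV, and validates the result.
#'
#' @param path matrix file.
#' @param format `"nexus"` or `"tnt"`.
#' @param partition sidecar CSV path (see [read_partition()]) or a character
#'   vector of labels.
#' @param outgroup outgroup taxon label.
#' @return a `char_matrix`.
#' @export
read_matrix <- function(path, format = c("nexus", "tnt"), partition, outgroup) {
  format <- match.arg(format)
  cells <- switch(format,
                  nexus = read_nexus_cells(path),
                  tnt = read_tnt_cells(path))
  if (is.character(partition) && length(partition) == 1L && file.exists(partition)) {
    p <- read_partition(partition, ncol(cells))
    character_matrix(cells, p$partition, outgroup, p$ordering)
  } else {
    character_matrix(cells, partition, outgroup)
  }
}

#' Write a character matrix to NEXUS or TNT
#'
#' The partition and ordering go to a sidecar CSV when `partition_path` is
#' given. Reading the pair back with [read_matrix()] reproduces the matrix
#' exactly (states, missing entries, partition labels).
#'
#' @param m a `char_matrix`.
#' @param path output file.
#' @param format `"nexus"` or `"tnt"`.
#' @param partition_path optional sidecar CSV path.
#' @export
write_matrix <- function(m, path, format = c("nexus", "tnt"),
                         partition_path = NULL) {
  format <- match.arg(format)
  if (!inherits(m, "char_matrix")) stop("`m` must be a char_matrix")
  if (nrow(m$cells) == 0L || ncol(m$cells) == 0L)
    stop("refusing to write an empty matrix")
  switch(format,
         nexus = write_nexus_cells(m, path),
         tnt = write_tnt_cells(m, path))
  if (!is.null(partition_path)) write_partition(m, partition_path)
  invisible(path)
}

# keep a subset of taxa/characters, preserving metadata
subset_matrix <- function(m, taxa = NULL, chars = NULL) {
  cells <- m$cells
  partition <- m$partition
  ordering <- m$ordering
  if (!is.null(taxa)) cells <- cells[taxa, , drop = FALSE]
  if (!is.null(chars)) {
    cells <- cells[, chars, drop = FALSE]
    partition <- partition[chars]
    ordering <- ordering[chars]
  }
  if (!m$outgroup %in% rownames(cells))
    stop("subset would remove the outgroup")
  if (ncol(cells) == 0L) {
    out <- list(cells = cells, partition = partition, outgroup = m$outgroup,
                ordering = ordering)
    class(out) <- "char_matrix"
    return(out)
  }
  character_matrix(cells, partition, m$outgroup, ordering)
}
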