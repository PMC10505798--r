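# Published-marker-table dialect: reading and arithmetic validation.
#
# The table mirrors the published layout: one row per marker with columns
#   gene, atg_pos, variation_id, marker_type, name, primer_f, primer_r,
#   reference_size, enzyme, haplotypes
# where reference_size uses the "elite/other" notation: the value before
# "/" belongs to elite haplotypes, the value after to the others.  A plain
# number is an undigested amplicon; a parenthesised list "(a, b)" gives
# enzyme-digested fragments; a parenthesised signed number "(+391)" or
# "(-17)" is the indel carried by that allele class (the amplicon printed
# on the other side belongs to the allele without it).

#' Read a marker table in the published reference-size dialect
#'
#' @param path TSV file.
#' @return data.frame, one row per marker, with parsed `elite` and `other`
#'   size descriptors attached as list-columns.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("gene", "atg_pos", "variation_id", "marker_type", "name",
            "primer_f", "primer_r", "reference_size", "enzyme", "haplotypes")
  if (!all(need %in% names(df)))
    stop("marker table needs columns: ", paste(need, collapse = ", "))
  sides <- lapply(df$reference_size, parse_reference_size)
  df$elite <- lapply(sides, `[[`, "elite")
  df$other <- lapply(sides, `[[`, "other")
  df
}

# split "a/(b, c)" into parsed elite (before /) and other (after /) parts
parse_reference_size <- function(x) {
  x <- gsub(" ", "", x)
  # the "/" separating the two allele classes is the one not inside parens
  depth <- 0L; split_at <- NA_integer_
  ch <- chars(x)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    else if (ch[i] == ")") depth <- depth - 1L
    else if (ch[i] == "/" && depth == 0L) { split_at <- i; break }
  }
  if (is.na(split_at)) stop("malformed reference size: ", x)
  list(elite = parse_size_part(substr(x, 1L, split_at - 1L)),
       other = parse_size_part(substr(x, split_at + 1L, nchar(x))))
}

parse_size_part <- function(x) {
  if (grepl("^\\(", x)) {
    inner <- sub("^\\(", "", sub("\\)$", "", x))
    if (grepl("^[+-]", inner))
      return(list(kind = "indel", size = as.integer(inner)))
    return(list(kind = "fragments",
                sizes = as.integer(strsplit(inner, ",")[[1L]])))
  }
  list(kind = "amplicon", size = as.integer(x))
}

#' Validate a marker table's arithmetic and primer conventions
#'
#' Per-row checks: primer lengths 18-24 nt; for CAPS/dCAPS rows, the
#' digested side's fragments sum to the undigested side's amplicon
#' (conservation); for dCAPS rows, the smallest fragment equals the length
#' of the mismatch-bearing primer (the primer carrying a lower-case base;
#' when a dCAPS row prints no lower-case base the forward primer is used
#' and the row is flagged in `lowercase_present`); for Indel rows, the two
#' implied amplicon lengths differ by exactly the indel size.
#'
#' @param df data.frame from [read_marker_table()].
#' @return data.frame of per-row logicals: `primer_len_ok`,
#'   `conservation_ok`, `dcaps_small_fragment_ok`, `indel_bands_ok`,
#'   `lowercase_present`, plus `elite_bands`/`other_bands` list-columns of
#'   implied band sizes.
#' @export
validate_marker_table <- function(df) {
  n <- nrow(df)
  out <- data.frame(name = df$name,
                    primer_len_ok = logical(n), conservation_ok = NA,
                    dcaps_small_fragment_ok = NA, indel_bands_ok = NA,
                    lowercase_present = NA, stringsAsFactors = FALSE)
  out$conservation_ok <- as.logical(out$conservation_ok)
  out$dcaps_small_fragment_ok <- as.logical(out$dcaps_small_fragment_ok)
  out$indel_bands_ok <- as.logical(out$indel_bands_ok)
  out$lowercase_present <- as.logical(out$lowercase_present)
  eb <- vector("list", n); ob <- vector("list", n)
  for (i in seq_len(n)) {
    lf <- nchar(df$primer_f[i]); lr <- nchar(df$primer_r[i])
    out$primer_len_ok[i] <- all(c(lf, lr) >= 18L & c(lf, lr) <= 24L)
    el <- df$elite[[i]]; ot <- df$other[[i]]
    mt <- df$marker_type[i]
    if (mt %in% c("CAPS", "dCAPS")) {
      amp <- if (el$kind == "amplicon") el else ot
      frg <- if (el$kind == "fragments") el else ot
      out$conservation_ok[i] <- sum(frg$sizes) == amp$size
      eb[[i]] <- if (el$kind == "amplicon") el$size else el$sizes
      ob[[i]] <- if (ot$kind == "amplicon") ot$size else ot$sizes
      if (mt == "dCAPS") {
        has_lc <- c(grepl("[acgt]", df$primer_f[i]),
                    grepl("[acgt]", df$primer_r[i]))
        out$lowercase_present[i] <- any(has_lc)
        mm_len <- if (has_lc[1L]) lf else if (has_lc[2L]) lr else lf
        out$dcaps_small_fragment_ok[i] <- min(frg$sizes) == mm_len
      }
    } else if (mt == "Indel") {
      ind <- if (el$kind == "indel") el else ot
      amp <- if (el$kind == "amplicon") el else ot
      b_with <- amp$size + ind$size       # allele carrying the indel
      eb[[i]] <- if (el$kind == "indel") b_with else el$size
      ob[[i]] <- if (ot$kind == "indel") b_with else ot$size
      out$indel_bands_ok[i] <- abs(eb[[i]] - ob[[i]]) == abs(ind$size) &&
        b_with >= 1L
    }
  }
  out$elite_bands <- eb
  out$other_bands <- ob
  out
}

#' Path to the bundled replica of the published marker table
#'
#' A transcription of the published eleven-marker table (genes, target
#' positions, primer sequences, reference sizes, enzymes, detected
#' haplotypes) in the package's marker-table dialect.
#'
#' @return file path.
#' @export
published_marker_table <- function() {
  system.file("extdata", "published_markers.tsv", package = "haplomarker",
              mustWork = TRUE)
}

#' Write designed markers as a marker table
#'
#' @param markers list of `marker_spec`s.
#' @param path output TSV.
#' @export
write_marker_table <- function(markers, path) {
  fmt_side <- function(b) {
    if (length(b) == 1L) as.character(b)
    else paste0("(", paste(b, collapse = ", "), ")")
  }
  rows <- lapply(markers, function(m) {
    data.frame(gene = m$gene_id %||% "", atg_pos = m$variant$atg_pos,
               variation_id = m$variant$variant_id, marker_type = m$mtype,
               name = m$name, primer_f = m$forward$seq,
               primer_r = m$reverse$seq,
               reference_size = paste0(fmt_side(m$elite_bands), "/",
                                       fmt_side(m$other_bands)),
               enzyme = if (is.null(m$enzyme)) "" else m$enzyme$name,
               haplotypes = paste(m$detected, collapse = ","),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
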