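#' Read an orthogroup membership table (OrthoFinder N0 dialect)
#'
#' Parses a tab-separated hierarchical-orthogroup table: one row per HOG,
#' columns `HOG`, `OG` (optional), `Gene Tree Parent Clade` (optional,
#' ignored), then one gene-list column per species. Gene lists are comma
#' (+ optional space) separated; an empty cell means the species has no
#' gene in that family.
#'
#' Gene ids are keyed per species, so the same id string may legally occur
#' in two different species. Within one species a gene may belong to at
#' most one HOG; a violation is a hard error naming the gene.
#'
#' @param path TSV file with a header row.
#' @param config a [study_config()]; its species must all be present as
#'   columns and define the column order of the result.
#' @return An object of class `orthogroup_table`: list with `genes` (long
#'   data.frame: `hog_id`, `species`, `gene_id`), `hogs` (data.frame:
#'   `hog_id`, `og_id`), and `species` (character, config order).
#' @export
read_orthogroups <- function(path, config) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  cn <- names(raw)
  hog_col <- cn[tolower(cn) %in% c("hog", "hog_id")][1]
  if (is.na(hog_col)) stop("orthogroup table: no HOG column in ", path)
  og_col <- cn[tolower(cn) %in% c("og", "og_id")][1]
  meta <- c(hog_col, og_col, cn[tolower(cn) == "gene tree parent clade"])
  sp_cols <- setdiff(cn, meta[!is.na(meta)])
  unknown <- setdiff(sp_cols, config$species$name)
  if (length(unknown))
    stop("orthogroup table: unknown species column(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(config$species$name, sp_cols)
  if (length(missing))
    stop("orthogroup table: missing species column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(raw[[hog_col]]))
    stop("orthogroup table: duplicated hog_id: ",
         raw[[hog_col]][duplicated(raw[[hog_col]])][1])

  species <- config$species$name
  long <- vector("list", length(species))
  for (i in seq_along(species)) {
    cells <- raw[[species[i]]]
    toks <- strsplit(cells, ",[ ]?")
    toks <- lapply(toks, function(x) x[nzchar(x)])
    n <- lengths(toks)
    long[[i]] <- data.frame(
      hog_id = rep(raw[[hog_col]], n),
      species = species[i],
      gene_id = unlist(toks, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    dup <- long[[i]]$gene_id[duplicated(long[[i]]$gene_id)]
    if (length(dup))
      stop("gene '", dup[1], "' (", species[i],
           ") appears in more than one HOG")
  }
  genes <- do.call(rbind, long)
  hogs <- data.frame(hog_id = raw[[hog_col]],
                     og_id = if (!is.na(og_col)) raw[[og_col]] else NA_character_,
                     stringsAsFactors = FALSE)
  new_orthogroup_table(genes, hogs, species)
}

new_orthogroup_table <- function(genes, hogs, species) {
  structure(list(genes = genes, hogs = hogs, species = species),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table:", nrow(x$hogs), "HOGs,", nrow(x$genes), "genes,",
      length(x$species), "species (", paste(x$species, collapse = ", "), ")\n")
  invisible(x)
}

#' Per-family gene counts
#'
#' @param x an `orthogroup_table` (or conserved subset thereof).
#' @return Integer matrix, one row per HOG (rownames = hog ids, input
#'   order), one column per species (config order).
#' @export
gene_counts <- function(x) {
  stopifnot(inherits(x, "orthogroup_table"))
  m <- table(factor(x$genes$hog_id, levels = x$hogs$hog_id),
             factor(x$genes$species, levels = x$species))
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  names(dimnames(m)) <- NULL
  m
}

#' Write an orthogroup table in the N0 dialect
#'
#' Deterministic inverse of [read_orthogroups()]: rows in the stored HOG
#' order, gene lists joined with `", "`, tabs, LF line endings.
#'
#' @param x an `orthogroup_table`.
#' @param path output path.
#' @export
write_orthogroups <- function(x, path) {
  stopifnot(inherits(x, "orthogroup_table"))
  cells <- sapply(x$species, function(sp) {
    sub <- x$genes[x$genes$species == sp, , drop = FALSE]
    joined <- vapply(split(sub$gene_id, factor(sub$hog_id, levels = x$hogs$hog_id)),
                     paste, "", collapse = ", ")
    joined
  })
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  header <- paste(c("HOG", "OG", x$species), collapse = "\t")
  og <- ifelse(is.na(x$hogs$og_id), "", x$hogs$og_id)
  lines <- paste(x$hogs$hog_id, og,
                 apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

pick_column <- function(cn, aliases, what, path) {
  hit <- cn[tolower(gsub("[._]", "", cn)) %in% aliases]
  if (!length(hit)) stop("missing ", what, " column in ", path)
  hit[1]
}

#' Read a per-species differential-expression table
#'
#' Expects a TSV with a gene-id column, a log2 fold-change column
#' (drought relative to control) and an adjusted-p column; a base-mean
#' column is kept when present. Case-insensitive aliases are accepted
#' (`gene`/`gene_id`/`id`, `log2FoldChange`/`log2fc`/`lfc`,
#' `padj`/`p_adj`/`fdr`/`adj_p_val`, `baseMean`/`base_mean`).
#'
#' A missing `padj` (`NA`, the independent-filtering convention of
#' count-based DE tools) is retained but such a gene can never be flagged
#' differentially expressed. An out-of-range `padj` or a non-numeric value
#' is an error reporting the offending data row.
#'
#' @param path TSV file.
#' @param species species name attached to the table.
#' @return A `de_table`: data.frame with columns `gene_id`, `log2fc`,
#'   `padj`, `base_mean`, and attribute `species`.
#' @export
read_de_table <- function(path, species) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  cn <- names(raw)
  g <- pick_column(cn, c("gene", "geneid", "id"), "gene", path)
  l <- pick_column(cn, c("log2foldchange", "log2fc", "lfc"), "log2FoldChange", path)
  p <- pick_column(cn, c("padj", "padjust", "fdr", "adjpval", "qvalue"), "padj", path)
  b <- cn[tolower(gsub("[._]", "", cn)) %in% c("basemean", "base")][1]

  num <- function(col, what, range = NULL) {
    x <- raw[[col]]
    is_na <- x %in% c("", "NA", "na", "NaN")
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is_na & is.na(v))
    if (length(bad))
      stop(path, ": non-numeric ", what, " at data row ", bad[1],
           " ('", x[bad[1]], "')")
    v[is_na] <- NA_real_
    if (!is.null(range)) {
      out <- which(!is.na(v) & (v < range[1] | v > range[2]))
      if (length(out))
        stop(path, ": ", what, " out of [", range[1], ",", range[2],
             "] at data row ", out[1], " (", v[out[1]], ")")
    }
    v
  }
  de <- data.frame(
    gene_id = raw[[g]],
    log2fc = num(l, "log2FoldChange"),
    padj = num(p, "padj", c(0, 1)),
    base_mean = if (!is.na(b)) num(b, "baseMean", c(0, Inf)) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(de$gene_id))
    stop(path, ": duplicated gene_id: ", de$gene_id[duplicated(de$gene_id)][1])
  structure(de, species = species, class = c("de_table", "data.frame"))
}

#' Read a diversifying-selection results table
#'
#' TSV with columns `gene` (alias `gene_id`), `p_corrected` (alias
#' `padj`/`p`), and optionally `tested` (`1/0` or `TRUE/FALSE`). When the
#' `tested` column is absent, a gene is considered tested iff its p-value
#' is present. Untested genes must carry no p-value.
#'
#' @param path TSV file.
#' @return Data.frame `gene_id`, `p_corrected`, `tested` of class
#'   `selection_table`.
#' @export
read_selection_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  cn <- names(raw)
  g <- pick_column(cn, c("gene", "geneid", "id"), "gene", path)
  p <- pick_column(cn, c("pcorrected", "padj", "p", "pvalue"), "p_corrected", path)
  t_col <- cn[tolower(cn) == "tested"][1]
  pv <- suppressWarnings(as.numeric(raw[[p]]))
  is_na <- raw[[p]] %in% c("", "NA", "na")
  bad <- which(!is_na & is.na(pv))
  if (length(bad))
    stop(path, ": non-numeric p_corrected at data row ", bad[1])
  pv[is_na] <- NA_real_
  out <- which(!is.na(pv) & (pv < 0 | pv > 1))
  if (length(out))
    stop(path, ": p_corrected out of [0,1] at data row ", out[1])
  tested <- if (!is.na(t_col)) {
    tolower(raw[[t_col]]) %in% c("1", "true", "yes")
  } else !is.na(pv)
  if (any(!tested & !is.na(pv)))
    stop(path, ": untested gene carries a p-value (row ",
         which(!tested & !is.na(pv))[1], ")")
  if (anyDuplicated(raw[[g]]))
    stop(path, ": duplicated gene_id: ", raw[[g]][duplicated(raw[[g]])][1])
  structure(data.frame(gene_id = raw[[g]], p_corrected = pv, tested = tested,
                       stringsAsFactors = FALSE),
            class = c("selection_table", "data.frame"))
}

#' Read a gene-to-GO annotation map
#'
#' TSV with columns `gene`, `species`, `go_terms` (comma-separated GO ids;
#' empty = unannotated). Terms are opaque identifiers.
#'
#' @param path TSV file.
#' @return Long data.frame `gene_id`, `species`, `term`.
#' @export
read_go_map <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  cn <- names(raw)
  g <- pick_column(cn, c("gene", "geneid", "id"), "gene", path)
  s <- pick_column(cn, c("species"), "species", path)
  t <- pick_column(cn, c("goterms", "go", "terms"), "go_terms", path)
  toks <- strsplit(raw[[t]], ",[ ]?")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  n <- lengths(toks)
  data.frame(gene_id = rep(raw[[g]], n), species = rep(raw[[s]], n),
             term = unlist(toks, use.names = FALSE), stringsAsFactors = FALSE)
}

#' Write the candidate-family table
#'
#' Deterministic TSV, one row per HOG sorted by `hog_id`; logical columns
#' are written as `1`/`0`, UTF-8, LF line endings. Identical input yields
#' byte-identical output.
#'
#' @param records data.frame from [build_tiers()].
#' @param path output path.
#' @export
write_candidate_table <- function(records, path) {
  df <- as.data.frame(records)
  if (nrow(df)) df <- df[order(df$hog_id), , drop = FALSE]
  for (j in seq_along(df)) if (is.logical(df[[j]])) df[[j]] <- as.integer(df[[j]])
  write_tsv_lf(df, path)
}

# deterministic TSV writer: header + tab-joined rows, LF endings
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt <- function(x) {
    out <- if (is.double(x)) formatC(x, format = "g", digits = 15)
           else as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df)) {
    cells <- vapply(df, fmt, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
    lines <- c(lines, apply(cells, 1, paste, collapse = "\t"))
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
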