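# Readers and writers for the plain-text genomics formats the pipeline
# touches. All internal coordinates are 0-based, half-open (BED
# convention); GTF-style 1-based starts are converted on input.

empty_gene_table <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             tss = integer(), gene_length = integer(), biotype = character(),
             stringsAsFactors = FALSE)
}

empty_peak_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit = integer(), score = numeric(), tf = character(),
             assay = character(), replicate = integer(),
             stringsAsFactors = FALSE)
}

#' Read a gene annotation
#'
#' Parses a gene annotation into a table of gene models, one row per gene,
#' with an explicit transcription start site (TSS). Internally coordinates
#' are 0-based half-open: for `+` strand genes the TSS is the interval
#' start, for `-` strand genes it is `end - 1`, the last base of the
#' half-open interval. Records with any strand other than `+`/`-` are
#' rejected rather than guessed, because signed summit-to-TSS distances
#' are strand-dependent.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed6"` (0-based half-open, columns chrom, start, end,
#'   gene_id, score, strand) or `"gtf_lite"` (tab-separated 9-column GTF
#'   with 1-based starts; only `gene` feature rows are used and `gene_id`
#'   is taken from the attributes column, `gene_biotype` when present).
#' @return A data frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `gene_length`, `biotype`.
#' @export
read_annotation <- function(path, dialect = c("bed6", "gtf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_gene_table())

  if (dialect == "bed6") {
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    bad <- which(nf < 6L)
    if (length(bad))
      stopf("malformed BED6 line %d: expected 6 fields, found %d",
            lineno[bad[1]], nf[bad[1]])
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    start <- suppressWarnings(as.numeric(m[, 2]))
    end <- suppressWarnings(as.numeric(m[, 3]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stopf("malformed BED6 line %d: non-numeric coordinates", lineno[bad[1]])
    bad <- which(start < 0 | end < 0)
    if (length(bad))
      stopf("malformed BED6 line %d: negative coordinate", lineno[bad[1]])
    bad <- which(start >= end)
    if (length(bad))
      stopf("malformed BED6 line %d: start must be < end", lineno[bad[1]])
    strand <- normalize_strand(m[, 6])
    bad <- which(!(strand %in% c("+", "-")))
    if (length(bad))
      stopf("line %d: unknown strand '%s' (only '+'/'-' accepted)",
            lineno[bad[1]], m[bad[1], 6])
    out <- data.frame(gene_id = m[, 4], chrom = m[, 1], strand = strand,
                      tss = as.integer(ifelse(strand == "+", start, end - 1)),
                      gene_length = as.integer(end - start),
                      biotype = NA_character_, stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 9L)
    if (length(bad))
      stopf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
            lineno[bad[1]], nf[bad[1]])
    m <- do.call(rbind, lapply(fields, `[`, 1:9))
    feat <- m[, 3] == "gene"
    if (!any(feat)) return(empty_gene_table())
    m <- m[feat, , drop = FALSE]
    lineno <- lineno[feat]
    start1 <- suppressWarnings(as.numeric(m[, 4]))
    end1 <- suppressWarnings(as.numeric(m[, 5]))
    bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
    if (length(bad))
      stopf("malformed GTF line %d: bad coordinates", lineno[bad[1]])
    strand <- normalize_strand(m[, 7])
    bad <- which(!(strand %in% c("+", "-")))
    if (length(bad))
      stopf("line %d: unknown strand '%s' (only '+'/'-' accepted)",
            lineno[bad[1]], m[bad[1], 7])
    gene_id <- extract_attr(m[, 9], "gene_id")
    bad <- which(is.na(gene_id))
    if (length(bad))
      stopf("line %d: attributes lack gene_id", lineno[bad[1]])
    biotype <- extract_attr(m[, 9], "gene_biotype")
    start <- start1 - 1  # to 0-based half-open
    out <- data.frame(gene_id = gene_id, chrom = m[, 1], strand = strand,
                      tss = as.integer(ifelse(strand == "+", start, end1 - 1)),
                      gene_length = as.integer(end1 - start),
                      biotype = biotype, stringsAsFactors = FALSE)
  }
  dup <- duplicated(out$gene_id)
  if (any(dup))
    stopf("duplicate gene_id in annotation: %s", out$gene_id[which(dup)[1]])
  rownames(out) <- NULL
  out
}

extract_attr <- function(attrs, key) {
  pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(x) {
    if (length(x) >= 2) x[2] else NA_character_
  }, character(1))
}

#' Read a peak set
#'
#' Parses called peaks from BED6 or ENCODE narrowPeak (10-column) files
#' and tags every record with its transcription factor, assay, and
#' replicate. For narrowPeak records the summit is `start + offset`
#' (column 10) when the offset is non-negative, otherwise the interval
#' midpoint `floor((start + end) / 2)`; BED6 peaks always use the
#' midpoint.
#'
#' @param path Path to the peak file.
#' @param dialect `"narrowpeak"` or `"bed6"`.
#' @param tf Transcription-factor label attached to every record.
#' @param assay `"cutrun"` or `"chip"`.
#' @param replicate Replicate number (integer >= 1).
#' @return A data frame with columns `chrom`, `start`, `end`, `summit`,
#'   `score`, `tf`, `assay`, `replicate`.
#' @export
read_peaks <- function(path, dialect = c("narrowpeak", "bed6"),
                       tf, assay = c("cutrun", "chip"), replicate = 1L) {
  dialect <- match.arg(dialect)
  assay <- match.arg(assay)
  if (!is.numeric(replicate) || replicate < 1)
    stopf("replicate must be an integer >= 1")
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- empty_peak_table()
    return(out)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  need <- if (dialect == "narrowpeak") 10L else 6L
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad))
    stopf("malformed %s line %d: expected %d fields, found %d",
          dialect, lineno[bad[1]], need, nf[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("malformed %s line %d: non-numeric coordinates",
          dialect, lineno[bad[1]])
  bad <- which(start < 0 | end < 0)
  if (length(bad))
    stopf("line %d: negative coordinate", lineno[bad[1]])
  bad <- which(start >= end)
  if (length(bad))
    stopf("line %d: start must be < end", lineno[bad[1]])
  score <- suppressWarnings(as.numeric(m[, 5]))
  score[is.na(score)] <- 0
  if (dialect == "narrowpeak") {
    offset <- suppressWarnings(as.numeric(m[, 10]))
    bad <- which(is.na(offset))
    if (length(bad))
      stopf("malformed narrowPeak line %d: non-numeric summit offset",
            lineno[bad[1]])
    summit <- ifelse(offset >= 0, start + offset, floor((start + end) / 2))
    bad <- which(summit < start | summit >= end)
    if (length(bad))
      stopf("line %d: summit offset places summit outside the peak",
            lineno[bad[1]])
  } else {
    summit <- floor((start + end) / 2)
  }
  data.frame(chrom = m[, 1], start = as.integer(start), end = as.integer(end),
             summit = as.integer(summit), score = score, tf = tf,
             assay = assay, replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

#' Read a peak-set manifest
#'
#' Reads every peak file listed in a manifest (columns `tf`, `assay`,
#' `replicate`, `path`, and optionally `dialect`) and checks the
#' replicate structure against the binding rules: each TF/assay must
#' supply exactly the declared replicates 1..total; a missing or
#' undeclared replicate is a configuration error.
#'
#' @param manifest Data frame (or path to a TSV) describing the peak files.
#' @param rules A [binding_rules()] object declaring replicate totals.
#' @return A single peak data frame (rows from all files combined).
#' @export
read_peak_sets <- function(manifest, rules = binding_rules()) {
  if (is.character(manifest)) manifest <- utils::read.delim(manifest)
  req <- c("tf", "assay", "replicate", "path")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stopf("peak manifest lacks column(s): %s", paste(miss, collapse = ", "))
  out <- list()
  for (tf in names(rules$tf_rules)) {
    r <- rules$tf_rules[[tf]]
    for (assay in c("cutrun", "chip")) {
      declared <- if (assay == "cutrun") r$cutrun_total else r$chip_total
      rows <- which(manifest$tf == tf & manifest$assay == assay)
      reps <- sort(manifest$replicate[rows])
      if (!identical(as.integer(reps), seq_len(declared)))
        stopf("manifest for %s/%s must list replicates 1..%d exactly",
              tf, assay, declared)
      for (i in rows) {
        out[[length(out) + 1L]] <- read_peaks(
          manifest$path[i],
          dialect = if ("dialect" %in% names(manifest))
            manifest$dialect[i] else "narrowpeak",
          tf = tf, assay = assay, replicate = manifest$replicate[i])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Construct a count table
#'
#' Bundles a gene-by-sample matrix of integer read counts with the
#' per-row spike-in flag and per-sample metadata. Every column of the
#' matrix must have exactly one metadata row.
#'
#' @param counts Integer matrix, rows = gene or spike-in ids, columns =
#'   sample ids.
#' @param spike_in Logical vector flagging spike-in rows.
#' @param meta Data frame with columns `sample_id`, `cell_type`,
#'   `genotype`, `n_cells`, `rel_volume`, `replicate`.
#' @export
count_table <- function(counts, spike_in, meta) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have row and column names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate row id in count table")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id in count table")
  if (any(counts < 0) || any(!is_whole(counts)))
    stopf("counts must be non-negative integers")
  if (length(spike_in) != nrow(counts))
    stopf("spike_in flag must have one entry per row")
  req <- c("sample_id", "cell_type", "genotype", "n_cells", "rel_volume",
           "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stopf("sample metadata lacks column(s): %s", paste(miss, collapse = ", "))
  unmatched <- setdiff(colnames(counts), meta$sample_id)
  if (length(unmatched))
    stopf("no metadata for sample '%s'", unmatched[1])
  if (anyDuplicated(meta$sample_id))
    stopf("duplicate sample_id in metadata")
  if (any(meta$rel_volume <= 0)) stopf("rel_volume must be > 0")
  if (any(meta$n_cells < 1)) stopf("n_cells must be >= 1")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, spike_in = spike_in, meta = meta),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes + %d spike-ins x %d samples\n",
              sum(!x$spike_in), sum(x$spike_in), ncol(x$counts)))
  invisible(x)
}

#' Read a count matrix and its sample metadata
#'
#' The counts file is a TSV whose first column holds gene or spike-in ids
#' and whose header names the samples; the metadata TSV must cover every
#' sample column. Rows whose id starts with `spike_prefix` are flagged as
#' spike-ins. Non-integer or negative counts are rejected.
#'
#' @param counts_path,meta_path Paths to the two TSV files.
#' @param spike_prefix Row-id prefix identifying spike-in rows
#'   (default `"ERCC-"`, the ERCC ExFold naming).
#' @return A [count_table()].
#' @export
read_counts <- function(counts_path, meta_path, spike_prefix = "ERCC-") {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stopf("count table needs an id column plus >= 1 sample")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stopf("duplicate row id: %s", ids[duplicated(ids)][1])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "numeric")
  if (any(is.na(mat))) stopf("non-numeric count value in %s", counts_path)
  if (any(mat < 0)) stopf("negative count value in %s", counts_path)
  if (any(!is_whole(mat))) stopf("non-integer count value in %s", counts_path)
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  count_table(mat, startsWith(ids, spike_prefix), meta)
}

# Declared output schemas: deterministic column order and types so every
# table round-trips bit-identically through read_result_table().
result_schemas <- list(
  binding = c(gene_id = "character", tf = "character", n_cutrun = "integer",
              n_chip = "integer", bound = "logical",
              nearest_distance = "numeric"),
  categories = c(gene_id = "character", category = "character"),
  de = c(gene_id = "character", fold_change = "numeric", p_value = "numeric",
         q_value = "numeric", passes = "logical"),
  ffl = c(x = "character", y = "character", z = "character",
          type = "character")
)

#' Write an analysis result table
#'
#' Writes records under one of the declared output schemas (`"binding"`,
#' `"categories"`, `"de"`, `"ffl"`) with a fixed column order. Numeric
#' columns are written with 17 significant digits so that reading the
#' file back with [read_result_table()] reproduces the records exactly.
#'
#' @param records Data frame conforming to the schema.
#' @param path Output TSV path.
#' @param schema Schema name.
#' @export
write_table <- function(records, path, schema) {
  spec <- result_schemas[[schema]]
  if (is.null(spec)) stopf("unknown output schema '%s'", schema)
  miss <- setdiff(names(spec), names(records))
  if (length(miss))
    stopf("records lack column(s) required by schema '%s': %s", schema,
          paste(miss, collapse = ", "))
  records <- records[, names(spec), drop = FALSE]
  out <- records
  for (j in seq_along(spec)) {
    if (spec[[j]] == "numeric") {
      v <- records[[j]]
      out[[j]] <- ifelse(is.na(v), "NA", formatC(v, digits = 17, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an analysis result table
#'
#' @param path TSV previously written by [write_table()].
#' @param schema Schema name (same set as [write_table()]).
#' @export
read_result_table <- function(path, schema) {
  spec <- result_schemas[[schema]]
  if (is.null(spec)) stopf("unknown output schema '%s'", schema)
  df <- utils::read.delim(path, colClasses = unname(spec),
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- names(spec)
  df
}
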