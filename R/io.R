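# Tabular IO --------------------------------------------------------------
#
# Every table the pipeline touches is TSV with optional '#'-prefixed
# "key: value" header lines and "NA" for missing values.  Genomic
# coordinates are 1-based inclusive throughout; the BED exporter converts
# to 0-based half-open.

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_acl(sprintf("file not found: %s", path))
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header <- character(0)
  if (any(is_comment)) {
    hl <- sub("^#\\s*", "", lines[is_comment])
    kv <- regmatches(hl, regexec("^([^:]+):\\s*(.*)$", hl))
    ok <- lengths(kv) == 3L
    header <- vapply(kv[ok], `[`, character(1), 3L)
    names(header) <- trimws(vapply(kv[ok], `[`, character(1), 2L))
  }
  body <- lines[!is_comment]
  if (length(body) == 0L) stop_acl(sprintf("no table body in %s", path))
  data <- utils::read.delim(text = paste(body, collapse = "\n"),
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = "NA")
  list(header = header, data = data)
}

write_tsv_raw <- function(data, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    writeLines(sprintf("# %s: %s", names(header), as.character(header)), con)
  }
  utils::write.table(data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

require_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_acl(sprintf("%s: missing required column(s): %s",
                     what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# Coerce a column to numeric, reporting the first offending cell by
# row/column coordinates instead of silently producing NA.
coerce_numeric <- function(data, col, what) {
  x <- data[[col]]
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad)) {
    stop_acl(sprintf("%s: non-numeric value '%s' at row %d, column '%s'",
                     what, x[bad[1]], bad[1], col))
  }
  out
}

# --- sample metadata ------------------------------------------------------

#' Validate a sample metadata table
#'
#' Checks the invariants of the cohort metadata: unique sample ids, finite
#' positive ages, two-level population labels, and (when present) cell
#' fraction and ancestry proportion columns that each sum to one.
#'
#' @param x Data frame with columns `sample_id`, `population`, `age`, `sex`,
#'   `infected`, `paraje`, and optionally `inbreeding_f`, `cell_*` fractions
#'   and `anc_*` ancestry proportions.
#' @return The validated data frame, invisibly classed as `sample_table`.
#' @export
validate_sample_table <- function(x) {
  require_columns(x, c("sample_id", "population", "age", "sex",
                       "infected", "paraje"), "sample table")
  if (anyDuplicated(x$sample_id)) stop_acl("sample table: duplicated sample_id")
  if (nrow(x) > 0) {
    if (any(!is.finite(x$age)) || any(x$age <= 0)) {
      stop_acl("sample table: ages must be finite and positive")
    }
    if (!all(x$sex %in% c("F", "M"))) stop_acl("sample table: sex must be F or M")
    if (!is.logical(x$infected)) x$infected <- as.logical(x$infected)
    cf <- grep("^cell_", names(x), value = TRUE)
    if (length(cf)) {
      for (i in seq_len(nrow(x))) {
        check_simplex(unlist(x[i, cf]),
                      sprintf("cell fractions for %s", x$sample_id[i]))
      }
    }
    ac <- grep("^anc_", names(x), value = TRUE)
    if (length(ac)) {
      for (i in seq_len(nrow(x))) {
        check_simplex(unlist(x[i, ac]),
                      sprintf("ancestry proportions for %s", x$sample_id[i]))
      }
    }
  }
  class(x) <- unique(c("sample_table", class(x)))
  invisible(x)
}

read_sample_table <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, c("sample_id", "population", "age", "sex",
                       "infected", "paraje"), basename(path))
  d$age <- coerce_numeric(d, "age", basename(path))
  d$infected <- as.logical(d$infected)
  for (col in grep("^(cell_|anc_)|^inbreeding_f$", names(d), value = TRUE)) {
    d[[col]] <- coerce_numeric(d, col, basename(path))
  }
  validate_sample_table(d)
  d
}

write_sample_table <- function(x, path) {
  write_tsv_raw(as.data.frame(x), path, c(schema = "samples"))
}

# --- beta matrix ----------------------------------------------------------

read_beta_matrix <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, "cpg", basename(path))
  samples <- setdiff(names(d), "cpg")
  m <- as.matrix(d[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d$cpg
  validate_beta_matrix(m)
  m
}

validate_beta_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop_acl("beta matrix must be a matrix with CpG rownames and sample colnames")
  }
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop_acl("beta values must lie in [0, 1] (or NA)")
  }
  invisible(m)
}

write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  d <- data.frame(cpg = rownames(m), m, check.names = FALSE)
  write_tsv_raw(d, path, c(schema = "beta"))
}

# --- clock definitions ----------------------------------------------------

read_clock_definition <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, c("cpg", "coefficient"), basename(path))
  h <- raw$header
  for (key in c("name", "intercept", "transform", "kind")) {
    if (!key %in% names(h)) {
      stop_acl(sprintf("%s: missing header key '%s'", basename(path), key))
    }
  }
  clock_definition(
    name = h[["name"]],
    kind = h[["kind"]],
    intercept = as.numeric(h[["intercept"]]),
    coefficients = stats::setNames(coerce_numeric(d, "coefficient",
                                                  basename(path)), d$cpg),
    transform = h[["transform"]],
    adult_age = if ("adult_age" %in% names(h)) as.numeric(h[["adult_age"]]) else 20
  )
}

write_clock_definition <- function(clock, path) {
  d <- data.frame(cpg = names(clock$coefficients),
                  coefficient = unname(clock$coefficients))
  write_tsv_raw(d, path, c(schema = "clock", name = clock$name,
                           kind = clock$kind,
                           intercept = format(clock$intercept, digits = 17),
                           transform = clock$transform,
                           adult_age = format(clock$adult_age, digits = 17)))
}

# --- genotypes ------------------------------------------------------------

#' Construct a genotype matrix object
#'
#' @param snps Data frame with columns `snp`, `chrom`, `pos` (1-based bp),
#'   `a1`, `a2`.
#' @param dosage Numeric matrix, SNPs in rows (matching `snps`), samples in
#'   columns; entries are counts of the `a1` allele in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, dosage) {
  require_columns(snps, c("snp", "chrom", "pos", "a1", "a2"), "snp table")
  if (nrow(snps) != nrow(dosage)) {
    stop_acl("snp table and dosage matrix disagree on SNP count")
  }
  if (!all(snps$a1 %in% c("A", "C", "G", "T")) ||
      !all(snps$a2 %in% c("A", "C", "G", "T"))) {
    stop_acl("alleles must be one of A, C, G, T")
  }
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_acl(sprintf("positions not strictly increasing on chromosome %s", ch))
    }
  }
  v <- dosage[!is.na(dosage)]
  if (length(v) && !all(v %in% 0:2)) stop_acl("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- snps$snp
  structure(list(snps = snps, dosage = dosage), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples (%d chromosomes)\n",
              nrow(x$snps), ncol(x$dosage), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

read_genotypes <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, c("snp", "chrom", "pos", "a1", "a2"), basename(path))
  d$pos <- coerce_numeric(d, "pos", basename(path))
  samples <- setdiff(names(d), c("snp", "chrom", "pos", "a1", "a2"))
  m <- as.matrix(d[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_matrix(d[, c("snp", "chrom", "pos", "a1", "a2")], m)
}

write_genotypes <- function(g, path) {
  d <- cbind(g$snps, as.data.frame(g$dosage, check.names = FALSE))
  write_tsv_raw(d, path, c(schema = "genotypes"))
}

# --- local ancestry -------------------------------------------------------

#' Construct a local-ancestry call set
#'
#' @param snps Data frame with columns `chrom`, `pos`, `snp`.
#' @param calls Character matrix, SNPs in rows, haplotypes in columns, with
#'   ancestry labels (e.g. `AMR`, `EUR`) or `UNK`.  Haplotype columns are
#'   named `<sample>_1` and `<sample>_2`.
#' @return An object of class `ancestry_calls`.
#' @export
ancestry_calls <- function(snps, calls) {
  require_columns(snps, c("chrom", "pos", "snp"), "ancestry snp table")
  if (nrow(snps) != nrow(calls)) stop_acl("snps/calls row mismatch")
  if (ncol(calls) %% 2 != 0) {
    stop_acl("ancestry calls need two haplotype columns per sample")
  }
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) stop_acl("ancestry call positions must be sorted")
  }
  rownames(calls) <- snps$snp
  structure(list(snps = snps, calls = calls), class = "ancestry_calls")
}

#' @export
print.ancestry_calls <- function(x, ...) {
  cat(sprintf("ancestry_calls: %d SNPs x %d haplotypes\n",
              nrow(x$snps), ncol(x$calls)))
  invisible(x)
}

read_ancestry_calls <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, c("chrom", "pos", "snp"), basename(path))
  d$pos <- coerce_numeric(d, "pos", basename(path))
  haps <- setdiff(names(d), c("chrom", "pos", "snp"))
  m <- as.matrix(d[, haps, drop = FALSE])
  ancestry_calls(d[, c("chrom", "pos", "snp")], m)
}

write_ancestry_calls <- function(x, path) {
  d <- cbind(x$snps, as.data.frame(x$calls, check.names = FALSE))
  write_tsv_raw(d, path, c(schema = "ancestry_calls"))
}

read_ancestry_posteriors <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, c("chrom", "pos", "snp", "haplotype", "ancestry",
                       "posterior"), basename(path))
  d$pos <- coerce_numeric(d, "pos", basename(path))
  d$posterior <- coerce_numeric(d, "posterior", basename(path))
  d
}

write_ancestry_posteriors <- function(x, path) {
  write_tsv_raw(x, path, c(schema = "ancestry_posteriors"))
}

# --- GWAS catalog ---------------------------------------------------------

validate_gwas_catalog <- function(d, what = "gwas catalog") {
  require_columns(d, c("snp", "chrom", "pos", "a1", "a2", "freq_a1",
                       "effect_a1", "se", "p", "n"), what)
  if (nrow(d)) {
    if (any(d$freq_a1 <= 0 | d$freq_a1 >= 1)) {
      stop_acl(sprintf("%s: freq_a1 must be in (0, 1)", what))
    }
    if (any(d$se <= 0)) stop_acl(sprintf("%s: se must be positive", what))
    if (any(d$p <= 0 | d$p > 1)) stop_acl(sprintf("%s: p must be in (0, 1]", what))
  }
  invisible(d)
}

read_gwas_catalog <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  for (col in c("pos", "freq_a1", "effect_a1", "se", "p", "n")) {
    if (col %in% names(d)) d[[col]] <- coerce_numeric(d, col, basename(path))
  }
  validate_gwas_catalog(d, basename(path))
  d
}

write_gwas_catalog <- function(x, path) {
  validate_gwas_catalog(x)
  write_tsv_raw(x, path, c(schema = "gwas_catalog"))
}

# --- kinship --------------------------------------------------------------

read_kinship <- function(path) {
  raw <- read_tsv_raw(path)
  d <- raw$data
  require_columns(d, c("id1", "id2", "pihat"), basename(path))
  d$pihat <- coerce_numeric(d, "pihat", basename(path))
  d
}

write_kinship <- function(x, path) {
  write_tsv_raw(x, path, c(schema = "kinship"))
}

# --- regions --------------------------------------------------------------

#' Write called regions as BED
#'
#' Internally region bounds are 1-based inclusive SNP positions; BED is
#' 0-based half-open, so `start` is decremented by one on export.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` and
#'   optionally `direction`, `z_max`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  require_columns(regions, c("chrom", "start", "end"), "regions")
  name <- if ("direction" %in% names(regions)) regions$direction else "."
  score <- if ("z_max" %in% names(regions)) {
    formatC(abs(regions$z_max), format = "f", digits = 3)
  } else {
    "."
  }
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = name, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- generic dispatcher ---------------------------------------------------

table_readers <- function() {
  list(samples = read_sample_table,
       beta = read_beta_matrix,
       clock = read_clock_definition,
       genotypes = read_genotypes,
       ancestry_calls = read_ancestry_calls,
       ancestry_posteriors = read_ancestry_posteriors,
       gwas_catalog = read_gwas_catalog,
       kinship = read_kinship)
}

table_writers <- function() {
  list(samples = write_sample_table,
       beta = write_beta_matrix,
       clock = write_clock_definition,
       genotypes = write_genotypes,
       ancestry_calls = write_ancestry_calls,
       ancestry_posteriors = write_ancestry_posteriors,
       gwas_catalog = write_gwas_catalog,
       kinship = write_kinship)
}

#' Read a typed pipeline table
#'
#' Dispatches to the schema-specific reader; every reader validates the
#' type's invariants and reports schema violations (missing columns,
#' non-parseable numeric cells) with coordinates.
#'
#' @param path Path to a TSV file with optional `#`-comment header lines.
#' @param schema One of `"samples"`, `"beta"`, `"clock"`, `"genotypes"`,
#'   `"ancestry_calls"`, `"ancestry_posteriors"`, `"gwas_catalog"`,
#'   `"kinship"`.
#' @return The typed table (data frame, matrix or S3 object depending on
#'   schema).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' cohort <- gen_cohort(cohort_spec(n_per_group = 3), seed = 1)
#' write_table(cohort, tf, schema = "samples")
#' identical(read_table(tf, "samples")$sample_id, cohort$sample_id)
read_table <- function(path, schema) {
  readers <- table_readers()
  if (!schema %in% names(readers)) {
    stop_acl(sprintf("unknown schema '%s' (expected one of: %s)", schema,
                     paste(names(readers), collapse = ", ")))
  }
  readers[[schema]](path)
}

#' Write a typed pipeline table
#'
#' @param x The table object.
#' @inheritParams read_table
#' @return The path, invisibly.
#' @export
write_table <- function(x, path, schema) {
  writers <- table_writers()
  if (!schema %in% names(writers)) {
    stop_acl(sprintf("unknown schema '%s'", schema))
  }
  writers[[schema]](x, path)
  invisible(path)
}
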