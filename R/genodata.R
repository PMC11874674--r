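#' Construct a genotype table
#'
#' A `genotype_table` holds diploid multilocus genotypes for embryos and
#' adults. Allele identity is the integer fragment size in bp (no binning).
#' Calls are stored as unordered pairs in canonical (low, high) order;
#' missing calls are `NA` in both slots.
#'
#' @param samples data.frame with columns `sample_id`, `clutch_id` (NA for
#'   adults), `year`, `role` (one of "embryo", "adult"); extra columns such as
#'   `host_species` are kept.
#' @param calls named list, one element per locus: an integer matrix with one
#'   row per sample (rownames = sample ids) and two columns of allele sizes.
#' @return an object of class `genotype_table` with elements `samples`,
#'   `loci`, `calls` and `alleles` (the observed allele universe per locus).
#' @export
genotype_table <- function(samples, calls) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "clutch_id", "year", "role") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  if (!all(samples$role %in% c("embryo", "adult")))
    stop("role must be 'embryo' or 'adult'")
  loci <- names(calls)
  if (is.null(loci) || any(loci == "") || anyDuplicated(loci))
    stop("calls must be a named list with unique locus names")
  calls <- lapply(calls, function(m) {
    m <- matrix(as.integer(m), ncol = 2L, dimnames = list(samples$sample_id, NULL))
    # canonical unordered storage; a half-missing call is treated as missing
    bad <- is.na(m[, 1L]) | is.na(m[, 2L])
    m[bad, ] <- NA_integer_
    sw <- !bad & m[, 1L] > m[, 2L]
    tmp <- m[sw, 1L]
    m[sw, 1L] <- m[sw, 2L]
    m[sw, 2L] <- tmp
    m
  })
  for (l in loci) {
    if (nrow(calls[[l]]) != nrow(samples))
      stop("locus ", l, ": call matrix rows do not match samples")
  }
  alleles <- lapply(calls, function(m) sort(unique(as.vector(m[!is.na(m[, 1L]), , drop = FALSE]))))
  structure(list(samples = samples, loci = loci, calls = calls, alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$samples), "individuals (",
      sum(x$samples$role == "embryo"), "embryos,",
      sum(x$samples$role == "adult"), "adults ) x", length(x$loci), "loci\n")
  invisible(x)
}

#' Number of individuals in a genotype table
#' @param gt a `genotype_table`
#' @return integer
#' @export
n_individuals <- function(gt) nrow(gt$samples)

#' Subset a genotype table by sample id
#' @param gt a `genotype_table`
#' @param ids character vector of sample ids to keep (order respected)
#' @return a `genotype_table`
#' @export
subset_samples <- function(gt, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, gt$samples$sample_id)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  idx <- match(ids, gt$samples$sample_id)
  genotype_table(gt$samples[idx, , drop = FALSE],
                 lapply(gt$calls, function(m) m[idx, , drop = FALSE]))
}

#' Genotype calls of selected samples at one locus
#' @param gt a `genotype_table`
#' @param locus locus name
#' @param ids sample ids (default all)
#' @return integer matrix, two columns, canonical order, `NA` for missing
#' @export
locus_calls <- function(gt, locus, ids = NULL) {
  if (!locus %in% gt$loci) stop("unknown locus: ", locus)
  m <- gt$calls[[locus]]
  if (is.null(ids)) m else m[match(as.character(ids), gt$samples$sample_id), , drop = FALSE]
}

#' Read a genotype table from CSV
#'
#' Primary dialect ("two_col"): two columns per locus named `<locus>_1` and
#' `<locus>_2`. Alternative dialect ("slash"): a single `<locus>` column with
#' calls written `a/b`. Missing data may be encoded as empty fields, `NA`, or
#' `0` (GenePop convention); all are mapped to missing.
#'
#' @param path CSV file with a header and columns `sample_id`, `clutch_id`,
#'   `year`, `role` followed by locus columns.
#' @param loci optional character vector declaring the expected panel; locus
#'   columns not in the panel raise an error.
#' @param dialect "two_col" (default) or "slash".
#' @return a `genotype_table`
#' @export
read_genotype_table <- function(path, loci = NULL, dialect = c("two_col", "slash")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("sample_id", "clutch_id", "year", "role")
  if (!all(meta_cols %in% names(df)))
    stop("genotype CSV must have columns ", paste(meta_cols, collapse = ", "))
  extra <- intersect(c("host_species"), names(df))
  samples <- df[, c(meta_cols, extra), drop = FALSE]
  samples$clutch_id[samples$clutch_id %in% c("", "NA")] <- NA
  locus_cols <- setdiff(names(df), c(meta_cols, extra))
  as_allele <- function(x) {
    x[x %in% c("", "NA", "0")] <- NA
    suppressWarnings(v <- as.integer(x))
    if (any(is.na(v) & !is.na(x)))
      stop("non-integer allele call in column")
    v[!is.na(v) & v == 0L] <- NA_integer_
    v
  }
  if (dialect == "two_col") {
    base <- sub("_[12]$", "", locus_cols)
    found <- unique(base)
    for (l in found) {
      want <- paste0(l, c("_1", "_2"))
      if (!all(want %in% locus_cols))
        stop("locus ", l, ": expected both columns ", paste(want, collapse = " and "))
    }
    if (!is.null(loci)) {
      unknown <- setdiff(found, loci)
      if (length(unknown)) stop("unknown locus column(s): ", paste(unknown, collapse = ", "))
      found <- intersect(loci, found)
    }
    calls <- lapply(found, function(l)
      cbind(as_allele(as.character(df[[paste0(l, "_1")]])),
            as_allele(as.character(df[[paste0(l, "_2")]]))))
    names(calls) <- found
  } else {
    found <- locus_cols
    if (!is.null(loci)) {
      unknown <- setdiff(found, loci)
      if (length(unknown)) stop("unknown locus column(s): ", paste(unknown, collapse = ", "))
      found <- intersect(loci, found)
    }
    calls <- lapply(found, function(l) {
      x <- as.character(df[[l]])
      x[x %in% c("", "NA")] <- NA
      parts <- strsplit(x, "/", fixed = TRUE)
      bad <- !is.na(x) & lengths(parts) != 2L
      if (any(bad))
        stop("odd allele count at locus ", l, " for sample(s) ",
             paste(df$sample_id[bad], collapse = ", "))
      a <- vapply(parts, function(p) if (length(p) == 2L) p[1L] else NA_character_, "")
      b <- vapply(parts, function(p) if (length(p) == 2L) p[2L] else NA_character_, "")
      cbind(as_allele(a), as_allele(b))
    })
    names(calls) <- found
  }
  genotype_table(samples, calls)
}

#' Write a genotype table to CSV (two-column dialect)
#' @param gt a `genotype_table`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_genotype_table <- function(gt, path) {
  out <- gt$samples
  for (l in gt$loci) {
    out[[paste0(l, "_1")]] <- gt$calls[[l]][, 1L]
    out[[paste0(l, "_2")]] <- gt$calls[[l]][, 2L]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a genotype table in GenePop format
#'
#' Three-digit allele coding; missing calls are `000000`. One population per
#' role (adults, then embryos).
#'
#' @param gt a `genotype_table`
#' @param path output file
#' @param title header line text
#' @return invisibly, `path`
#' @export
write_genepop <- function(gt, path, title = "clutchkin export") {
  if (any(unlist(gt$alleles) > 999L))
    stop("allele sizes exceed 3-digit GenePop coding")
  enc <- function(idx) {
    vapply(gt$loci, function(l) {
      m <- gt$calls[[l]][idx, , drop = FALSE]
      ifelse(is.na(m[, 1L]), "000000", sprintf("%03d%03d", m[, 1L], m[, 2L]))
    }, character(length(idx)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, gt$loci), con)
  for (r in c("adult", "embryo")) {
    idx <- which(gt$samples$role == r)
    if (!length(idx)) next
    writeLines("Pop", con)
    g <- matrix(enc(idx), nrow = length(idx))
    writeLines(paste0(gt$samples$sample_id[idx], " ,  ",
                      apply(g, 1L, paste, collapse = " ")), con)
  }
  invisible(path)
}

#' Read an aligned FASTA of mtDNA control-region sequences
#' @param path FASTA file of equal-length aligned sequences
#' @return a `haplotype_alignment`: list with `seqs` (named uppercase character
#'   vector) and `length` (alignment columns)
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  haplotype_alignment(seqs)
}

#' Construct a haplotype alignment from named sequences
#' @param seqs named character vector of aligned sequences (equal length)
#' @return a `haplotype_alignment`
#' @export
haplotype_alignment <- function(seqs) {
  if (!length(seqs)) stop("empty alignment")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by sample id")
  structure(list(seqs = seqs, length = len), class = "haplotype_alignment")
}

#' Collapse aligned sequences into haplotypes
#'
#' Columns containing a gap, `N`, or any IUPAC ambiguity code in any sequence
#' are removed before identity grouping ("complete" deletion), mirroring the
#' single global alignment length reported by DnaSP-style haplotyping. In
#' "pairwise" mode sites are dropped per comparison instead, and sequences
#' that match at all jointly unambiguous sites are merged (union-find).
#'
#' @param aln a `haplotype_alignment`
#' @param mode "complete" (default) or "pairwise"
#' @return a `haplotype_table`: list with `haplotype_of` (sample -> label),
#'   `haplotype_seqs` (label -> stripped sequence; in pairwise mode a class
#'   representative), `stripped_length` and `mode`. Labels are dense H1..Hk in
#'   order of first appearance.
#' @export
collapse_haplotypes <- function(aln, mode = c("complete", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "haplotype_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- names(aln$seqs)
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  if (mode == "complete") {
    keep <- apply(good, 2L, all)
    if (!any(keep)) stop("no informative sites: every column is ambiguous or gapped")
    stripped <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    labs_first <- stripped[!duplicated(stripped)]
    haplotype_of <- paste0("H", match(stripped, labs_first))
    names(haplotype_of) <- rownames(m)
    haplotype_seqs <- labs_first
    names(haplotype_seqs) <- paste0("H", seq_along(labs_first))
    stripped_length <- sum(keep)
  } else {
    n <- nrow(m)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- good[i, ] & good[j, ]
      if (any(ok) && all(m[i, ok] == m[j, ok])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    first <- !duplicated(roots)
    lab_of_root <- stats::setNames(paste0("H", seq_len(sum(first))), roots[first])
    haplotype_of <- stats::setNames(lab_of_root[as.character(roots)], rownames(m))
    keep <- apply(good, 2L, all)
    stripped_length <- sum(keep)
    rep_idx <- which(first)
    haplotype_seqs <- stats::setNames(
      apply(m[rep_idx, , drop = FALSE], 1L, function(x) paste(x, collapse = "")),
      lab_of_root[as.character(roots[rep_idx])])
  }
  structure(list(haplotype_of = haplotype_of, haplotype_seqs = haplotype_seqs,
                 stripped_length = stripped_length, mode = mode),
            class = "haplotype_table")
}

#' Construct a haplotype table directly from labels
#'
#' Used by the simulator and by tests; the label-level equivalent of
#' [collapse_haplotypes()].
#' @param haplotype_of named character vector, sample id -> haplotype label
#' @param haplotype_seqs optional named character vector, label -> sequence
#' @param stripped_length optional integer
#' @return a `haplotype_table`
#' @export
haplotype_table <- function(haplotype_of, haplotype_seqs = NULL, stripped_length = NA_integer_) {
  structure(list(haplotype_of = haplotype_of, haplotype_seqs = haplotype_seqs,
                 stripped_length = stripped_length, mode = "labels"),
            class = "haplotype_table")
}

#' Write haplotype assignments as TSV
#' @param ht a `haplotype_table`
#' @param gt optional `genotype_table` used to annotate clutch ids
#' @param path output file
#' @return invisibly, `path`
#' @export
write_haplotype_table <- function(ht, gt = NULL, path) {
  df <- data.frame(sample_id = names(ht$haplotype_of),
                   haplotype = unname(ht$haplotype_of),
                   stringsAsFactors = FALSE)
  df$clutch_id <- if (!is.null(gt))
    gt$samples$clutch_id[match(df$sample_id, gt$samples$sample_id)] else NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read haplotype assignments from TSV
#' @param path TSV with columns `sample_id`, `haplotype`
#' @return a `haplotype_table`
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  haplotype_table(stats::setNames(df$haplotype, df$sample_id))
}

#' Split a genotype table's embryos into clutches
#' @param gt a `genotype_table`
#' @return named list of clutches, each a list with `clutch_id`,
#'   `embryo_ids`, `host_species` (NA when unknown) and `year`; clutches in
#'   order of first appearance
#' @export
split_by_clutch <- function(gt) {
  emb <- gt$samples[gt$samples$role == "embryo", , drop = FALSE]
  if (!nrow(emb)) return(list())
  if (anyNA(emb$clutch_id))
    stop("embryo(s) without clutch id: ",
         paste(emb$sample_id[is.na(emb$clutch_id)], collapse = ", "))
  ids <- unique(emb$clutch_id)
  out <- lapply(ids, function(cid) {
    rows <- emb[emb$clutch_id == cid, , drop = FALSE]
    list(clutch_id = cid,
         embryo_ids = rows$sample_id,
         host_species = if ("host_species" %in% names(rows)) rows$host_species[1L] else NA,
         year = rows$year[1L])
  })
  names(out) <- ids
  out
}

#' Read a YAML run configuration, merged over defaults
#' @param path YAML file (key/value), or NULL for pure defaults
#' @return named list of settings
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    dialect = "two_col",
    haplotype_stripping = "complete",
    unbiased_he = TRUE,
    exclusion_form = "parent_pair",
    freq_mode = "uniform_minimal",
    exact_cap = 12L,
    mismatch_budget = 0L,
    n_sims = 10000L,
    tie_alpha = 0.05,
    seed = 1L
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
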