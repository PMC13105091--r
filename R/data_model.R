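# Canonical interaction-table columns. All joins key on string IDs.
.CANONICAL_COLS <- c("odorant_id", "smiles", "receptor_id", "sequence",
                     "response", "label", "weight", "tier")

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an odorant-receptor interaction dataset
#'
#' The universal experiment currency of the package: a set of odorants (SMILES
#' strings), a set of receptors (amino-acid sequences), and the measured
#' interactions between them. An interaction carries either a continuous
#' `response` (regression mode, e.g. spikes per second in an
#' electrophysiology panel) or a binary `label` (classification mode, e.g.
#' responsive / non-responsive in a screening compilation), plus an optional
#' non-negative `weight` and quality `tier`.
#'
#' @param odorants data.frame with columns `odorant_id`, `smiles`.
#' @param receptors data.frame with columns `receptor_id`, `sequence`.
#' @param interactions data.frame with columns `odorant_id`, `receptor_id`,
#'   and `response` (regression) or `label` (classification); optional
#'   `weight` (default 1) and `tier` (default `NA`).
#' @param mode `"regression"` or `"classification"`.
#' @return An object of class `interaction_dataset`.
#' @export
interaction_dataset <- function(odorants, receptors, interactions,
                                mode = c("regression", "classification")) {
  mode <- match.arg(mode)
  odorants <- as.data.frame(odorants, stringsAsFactors = FALSE)
  receptors <- as.data.frame(receptors, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (!all(c("odorant_id", "smiles") %in% names(odorants)))
    stop("`odorants` needs columns odorant_id, smiles")
  if (!all(c("receptor_id", "sequence") %in% names(receptors)))
    stop("`receptors` needs columns receptor_id, sequence")
  if (anyDuplicated(odorants$odorant_id))
    stop("duplicate odorant_id: ",
         paste(unique(odorants$odorant_id[duplicated(odorants$odorant_id)]),
               collapse = ", "))
  if (anyDuplicated(receptors$receptor_id))
    stop("duplicate receptor_id: ",
         paste(unique(receptors$receptor_id[duplicated(receptors$receptor_id)]),
               collapse = ", "))
  if (any(!nzchar(odorants$smiles)) || anyNA(odorants$smiles))
    stop("every odorant needs a non-empty SMILES string")
  if (any(!nzchar(receptors$sequence)) || anyNA(receptors$sequence))
    stop("every receptor needs a non-empty sequence")
  bad_seq <- vapply(strsplit(toupper(receptors$sequence), ""), function(ch)
    !all(ch %in% c(.AA_ALPHABET, "X")), logical(1))
  if (any(bad_seq))
    stop("receptor sequence(s) outside the amino-acid alphabet: ",
         paste(receptors$receptor_id[bad_seq], collapse = ", "))
  receptors$sequence <- toupper(receptors$sequence)

  value_col <- if (mode == "regression") "response" else "label"
  if (!value_col %in% names(interactions))
    stop("interactions need a `", value_col, "` column in ", mode, " mode")
  if (mode == "regression") {
    if (!is.numeric(interactions$response) || anyNA(interactions$response) ||
        any(!is.finite(interactions$response)))
      stop("responses must be finite numbers")
  } else {
    if (anyNA(interactions$label) || !all(interactions$label %in% c(0, 1)))
      stop("labels must be 0 or 1")
    interactions$label <- as.integer(interactions$label)
  }
  if (is.null(interactions$weight)) interactions$weight <- 1
  if (any(!is.finite(interactions$weight)) || any(interactions$weight < 0))
    stop("weights must be finite and >= 0")
  if (is.null(interactions$tier)) interactions$tier <- NA_character_

  miss_o <- setdiff(interactions$odorant_id, odorants$odorant_id)
  if (length(miss_o))
    stop("interactions reference unknown odorant_id: ",
         paste(utils::head(miss_o, 5), collapse = ", "))
  miss_r <- setdiff(interactions$receptor_id, receptors$receptor_id)
  if (length(miss_r))
    stop("interactions reference unknown receptor_id: ",
         paste(utils::head(miss_r, 5), collapse = ", "))
  key <- paste(interactions$odorant_id, interactions$receptor_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (odorant_id, receptor_id) pairs: ",
         paste(utils::head(unique(gsub("\r", " / ", key[duplicated(key)])), 5),
               collapse = ", "))

  keep <- intersect(c("odorant_id", "receptor_id", value_col, "weight", "tier"),
                    names(interactions))
  structure(list(odorants = odorants[, c("odorant_id", "smiles")],
                 receptors = receptors[, c("receptor_id", "sequence")],
                 interactions = interactions[, keep],
                 mode = mode),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("interaction_dataset (%s): %d odorants x %d receptors, %d interactions\n",
              x$mode, nrow(x$odorants), nrow(x$receptors), nrow(x$interactions)))
  full <- nrow(x$odorants) * nrow(x$receptors)
  cat(sprintf("  pair coverage: %.1f%%%s\n", 100 * nrow(x$interactions) / full,
              if (nrow(x$interactions) == full) " (full factorial)" else ""))
  if (!all(is.na(x$interactions$tier)))
    cat("  tiers:", paste(names(table(x$interactions$tier)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of interactions in a dataset
#' @param dataset an `interaction_dataset`.
#' @return Integer count of interaction records.
#' @export
n_interactions <- function(dataset) nrow(dataset$interactions)

#' Load an interaction table from delimited text
#'
#' Reads a CSV/TSV interaction table into a validated
#' [interaction_dataset()]. Column names are mapped through `schema`, so files
#' with arbitrary headers can be ingested. Exactly repeated
#' (odorant, receptor) rows are collapsed: responses are averaged in
#' regression mode, labels resolved by majority in classification mode; a
#' deterministic tie (no majority) is an error naming the pair. The number of
#' collapsed rows is recorded in attribute `n_deduplicated` and raised as a
#' warning.
#'
#' @param file path to a delimited text file, or literal text containing at
#'   least one newline.
#' @param mode `"regression"` or `"classification"`.
#' @param schema named character vector mapping canonical column names
#'   (`odorant_id`, `smiles`, `receptor_id`, `sequence`, `response`, `label`,
#'   `weight`, `tier`) to the file's column names. Canonical names present in
#'   the file need no mapping.
#' @param sep field separator (default `","`).
#' @param receptors optional data.frame of receptor records (e.g. from
#'   [load_receptor_fasta()]) supplying sequences when the table has none.
#' @return An `interaction_dataset`; attribute `n_deduplicated` counts
#'   collapsed duplicate rows.
#' @export
load_interaction_table <- function(file, mode = c("regression", "classification"),
                                   schema = NULL, sep = ",", receptors = NULL) {
  mode <- match.arg(mode)
  if (grepl("\n", file)) {
    con <- textConnection(file)
    on.exit(close(con))
    tab <- utils::read.table(con, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "", quote = "\"")
  } else {
    tab <- utils::read.table(file, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "", quote = "\"")
  }
  # resolve schema: canonical -> actual
  for (canon in names(schema)) {
    actual <- schema[[canon]]
    if (!actual %in% names(tab))
      stop("schema maps `", canon, "` to missing column `", actual, "`")
    names(tab)[names(tab) == actual] <- canon
  }
  value_col <- if (mode == "regression") "response" else "label"
  need <- c("smiles", value_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"odorant_id" %in% names(tab)) tab$odorant_id <- tab$smiles
  if (!"receptor_id" %in% names(tab)) {
    if (!"sequence" %in% names(tab))
      stop("table needs a receptor_id or sequence column")
    tab$receptor_id <- tab$sequence
  }
  if (mode == "classification" && !all(tab$label %in% c(0, 1))) {
    bad <- unique(tab$label[!tab$label %in% c(0, 1)])
    stop("labels must be 0 or 1; found: ", paste(bad, collapse = ", "))
  }

  key <- paste(tab$odorant_id, tab$receptor_id, sep = "\r")
  ndup <- 0L
  if (anyDuplicated(key)) {
    groups <- split(seq_len(nrow(tab)), key)
    rows <- vapply(groups, `[`, integer(1), 1L)
    if (mode == "regression") {
      agg <- vapply(groups, function(i) mean(tab$response[i]), numeric(1))
    } else {
      agg <- vapply(groups, function(i) {
        counts <- table(tab$label[i])
        if (length(counts) > 1 && counts[[1]] == counts[[2]])
          stop("conflicting duplicate labels with no majority for pair (",
               tab$odorant_id[i[1]], ", ", tab$receptor_id[i[1]], ")")
        as.numeric(names(counts)[which.max(counts)])
      }, numeric(1))
    }
    ndup <- nrow(tab) - length(groups)
    tab <- tab[rows, , drop = FALSE]
    tab[[value_col]] <- agg[paste(tab$odorant_id, tab$receptor_id, sep = "\r")]
    warning(ndup, " duplicate row(s) collapsed")
  }

  odorants <- unique(tab[, c("odorant_id", "smiles")])
  if ("sequence" %in% names(tab)) {
    recs <- unique(tab[, c("receptor_id", "sequence")])
  } else if (!is.null(receptors)) {
    recs <- as.data.frame(receptors, stringsAsFactors = FALSE)
    recs <- recs[recs$receptor_id %in% tab$receptor_id, , drop = FALSE]
    missing_seq <- setdiff(unique(tab$receptor_id), recs$receptor_id)
    if (length(missing_seq))
      stop("no sequence supplied for receptor(s): ",
           paste(missing_seq, collapse = ", "))
  } else {
    # sequences unknown; use the 'unknown residue' placeholder
    recs <- data.frame(receptor_id = unique(tab$receptor_id),
                       sequence = "X", stringsAsFactors = FALSE)
  }
  cols <- intersect(c("odorant_id", "receptor_id", value_col, "weight", "tier"),
                    names(tab))
  ds <- interaction_dataset(odorants, recs, tab[, cols], mode = mode)
  attr(ds, "n_deduplicated") <- ndup
  ds
}

#' Write an interaction table to CSV
#'
#' Inverse of [load_interaction_table()]: writes the canonical columns
#' (`odorant_id,smiles,receptor_id,sequence,response|label,weight,tier`) so
#' that loading the file again reproduces the dataset.
#'
#' @param dataset an `interaction_dataset`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_interaction_table <- function(dataset, file) {
  it <- dataset$interactions
  it$smiles <- dataset$odorants$smiles[match(it$odorant_id, dataset$odorants$odorant_id)]
  it$sequence <- dataset$receptors$sequence[match(it$receptor_id, dataset$receptors$receptor_id)]
  value_col <- if (dataset$mode == "regression") "response" else "label"
  out <- it[, c("odorant_id", "smiles", "receptor_id", "sequence",
                value_col, "weight", "tier")]
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Load receptor records from a FASTA file
#'
#' Reads amino-acid sequences with [Biostrings::readAAStringSet()]. The
#' receptor ID is the first whitespace-delimited token of each header;
#' sequences are upper-cased with line breaks joined.
#'
#' @param file path to a FASTA file, or literal FASTA text (detected by a
#'   leading `>` plus newline).
#' @return data.frame with columns `receptor_id`, `sequence`.
#' @export
load_receptor_fasta <- function(file) {
  if (grepl("\n", file)) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(file, tmp)
    file <- tmp
  }
  aas <- Biostrings::readAAStringSet(file)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(aas))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for entr(y/ies): ", paste(ids[empty], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(receptor_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Globally z-score the responses of a regression dataset
#'
#' Standardizes all responses with a single mean and standard deviation
#' computed over the pooled dataset -- not per receptor -- so that relative
#' response magnitudes across receptors are preserved. The population
#' (divisor-n) standard deviation is used.
#'
#' @param dataset a regression-mode `interaction_dataset`.
#' @return list with elements `dataset` (responses standardized) and `params`
#'   (list `mu`, `sigma` of the transformation).
#' @export
zscore_global <- function(dataset) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  if (dataset$mode != "regression")
    stop("zscore_global requires a regression dataset")
  y <- dataset$interactions$response
  if (length(y) < 2) stop("need at least 2 interactions")
  mu <- mean(y)
  sigma <- sqrt(mean((y - mu)^2))
  if (sigma == 0) stop("responses are constant; sigma = 0")
  dataset$interactions$response <- (y - mu) / sigma
  list(dataset = dataset, params = list(mu = mu, sigma = sigma))
}

#' Build the neural representation of odorants
#'
#' Represents each odorant as the vector of responses it elicits across the
#' receptor panel: a matrix of shape n_odorants x n_receptors whose (i, j)
#' entry is the response of odorant i at receptor j. Columns follow the
#' dataset's receptor declaration order. This treats the measured panel itself
#' as a feature space, comparable to any molecular representation through the
#' shape metrics.
#'
#' @param dataset a regression-mode `interaction_dataset`.
#' @param missing_policy `"error"` (default) to fail on absent pairs, or
#'   `"fill_zero"` to substitute 0.
#' @return A [representation_matrix()] named `"neural_representation"`.
#' @export
build_neural_representation <- function(dataset,
                                        missing_policy = c("error", "fill_zero")) {
  missing_policy <- match.arg(missing_policy)
  if (dataset$mode != "regression")
    stop("neural representation requires a regression dataset")
  ods <- dataset$odorants$odorant_id
  recs <- dataset$receptors$receptor_id
  m <- matrix(NA_real_, length(ods), length(recs),
              dimnames = list(ods, recs))
  it <- dataset$interactions
  m[cbind(match(it$odorant_id, ods), match(it$receptor_id, recs))] <- it$response
  if (anyNA(m)) {
    if (missing_policy == "error") {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("missing response for pair (", ods[idx[1]], ", ", recs[idx[2]],
           "); use missing_policy = \"fill_zero\" to impute")
    }
    m[is.na(m)] <- 0
  }
  representation_matrix(m, item_ids = ods, name = "neural_representation")
}

#' Construct a representation matrix
#'
#' An items x features numeric matrix with aligned item IDs; the common
#' currency passed between featurizers, shape metrics, and models.
#'
#' @param values numeric matrix (rows = items).
#' @param item_ids character vector of row identifiers.
#' @param name representation name.
#' @return object of class `representation_matrix` with fields `item_ids`,
#'   `values`, `name`.
#' @export
representation_matrix <- function(values, item_ids, name = "representation") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(item_ids))
    stop("row count (", nrow(values), ") != number of item_ids (",
         length(item_ids), ")")
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (any(!is.finite(values))) stop("all entries must be finite")
  rownames(values) <- item_ids
  structure(list(item_ids = as.character(item_ids), values = values,
                 name = name),
            class = "representation_matrix")
}

#' @export
print.representation_matrix <- function(x, ...) {
  cat(sprintf("representation_matrix '%s': %d items x %d features\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.representation_matrix <- function(x) dim(x$values)

#' Read / write representation matrices
#'
#' CSV layout: `item_id` first column, features after. `format = "rds"`
#' offers a compact binary cache for large representations.
#'
#' @param rep a `representation_matrix`.
#' @param file path.
#' @param name representation name to assign on read (default: file stem).
#' @param format `"csv"` (portable) or `"rds"` (binary cache).
#' @return `write_representation` returns `file` invisibly;
#'   `read_representation` returns a `representation_matrix`.
#' @export
write_representation <- function(rep, file, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(rep, file)
    return(invisible(file))
  }
  df <- data.frame(item_id = rep$item_ids, rep$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_representation
#' @export
read_representation <- function(file, name = NULL, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "item_id") stop("first column must be item_id")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  representation_matrix(as.matrix(df[, -1, drop = FALSE]),
                        item_ids = df$item_id, name = name)
}
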