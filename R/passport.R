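#' Accession passport records
#'
#' Passport metadata travels separately from the genotype matrix, keyed by
#' accession id and sample source.  Biological status is restricted to the
#' four categories genebanks use for this material: landrace, breeding
#' line, improved variety, unclassified.
#'
#' @param accession_id character vector.
#' @param name accession name (character, may be `NA`).
#' @param country country of origin (character, may be `NA`).
#' @param biological_status one of `"landrace"`, `"breeding_line"`,
#'   `"improved_variety"`, `"unclassified"`.
#' @param collection source collection label, e.g. `"CIP"`, `"USDA"`.
#' @param sample_source one of `"mother_plant"`, `"in_vitro"`,
#'   `"unspecified"`.
#' @param paired_with optional sample id (`"id|source"`) of this
#'   accession's counterpart sample; must reference the same accession with
#'   a different source.
#' @return data.frame of class `passport_table` with the above columns plus
#'   `sample_id`.
#' @export
passport_table <- function(accession_id, name = NA, country = NA,
                           biological_status = "unclassified",
                           collection = NA, sample_source = "unspecified",
                           paired_with = NA) {
  n <- length(accession_id)
  df <- data.frame(
    accession_id = as.character(accession_id),
    name = rep_len(as.character(name), n),
    country = rep_len(as.character(country), n),
    biological_status = rep_len(as.character(biological_status), n),
    collection = rep_len(as.character(collection), n),
    sample_source = rep_len(as.character(sample_source), n),
    paired_with = rep_len(as.character(paired_with), n),
    stringsAsFactors = FALSE
  )
  validate_passport(df)
  df$sample_id <- ifelse(
    df$sample_source == "unspecified", df$accession_id,
    paste0(df$accession_id, "|",
           c(mother_plant = "mother", in_vitro = "invitro")[df$sample_source])
  )
  class(df) <- c("passport_table", "data.frame")
  df
}

.biological_statuses <- c("landrace", "breeding_line", "improved_variety",
                          "unclassified")
.sample_sources <- c("mother_plant", "in_vitro", "unspecified")

validate_passport <- function(df) {
  bad <- !df$biological_status %in% .biological_statuses
  if (any(bad)) {
    stop("invalid biological_status: ",
         paste(unique(df$biological_status[bad]), collapse = ", "),
         " (must be one of ", paste(.biological_statuses, collapse = ", "),
         ")")
  }
  bad <- !df$sample_source %in% .sample_sources
  if (any(bad)) {
    stop("invalid sample_source: ",
         paste(unique(df$sample_source[bad]), collapse = ", "))
  }
  key <- paste(df$accession_id, df$sample_source)
  if (anyDuplicated(key)) {
    stop("duplicate (accession_id, sample_source) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  linked <- which(!is.na(df$paired_with))
  for (i in linked) {
    tgt <- parse_sample_ids(df$paired_with[i])
    if (tgt$accession_id != df$accession_id[i]) {
      stop("paired_with of ", df$accession_id[i],
           " references a different accession: ", df$paired_with[i])
    }
  }
  invisible(df)
}

#' Read / write a passport table
#'
#' Plain comma-delimited serialization of [passport_table()].
#'
#' @param path file path.
#' @return for `read_passport`, a `passport_table`.
#' @export
read_passport <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("accession_id", "name", "country", "biological_status",
            "collection", "sample_source", "paired_with")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("passport file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$paired_with[df$paired_with == ""] <- NA_character_
  passport_table(df$accession_id, df$name, df$country,
                 df$biological_status, df$collection, df$sample_source,
                 df$paired_with)
}

#' @rdname read_passport
#' @param pp a `passport_table`.
#' @export
write_passport <- function(pp, path) {
  out <- as.data.frame(pp)
  out$sample_id <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
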