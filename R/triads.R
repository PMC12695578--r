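#' Read the offspring covariate table
#'
#' Reads a tab-separated covariate file with header columns `individual_id`,
#' `affected` (0/1), `smoking` (0/1), `drinking` (0/1) and `bmi` (numeric,
#' kg/m^2). A `bmi_class` factor is derived at the 28 kg/m^2 obesity cut
#' (levels `"<28"` and `">=28"`).
#'
#' @param path Path to the TSV file.
#' @return Data frame with the columns above plus `bmi_class`.
#' @export
read_covariates <- function(path) {
  cov <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(individual_id = "character"),
                           stringsAsFactors = FALSE)
  need <- c("individual_id", "affected", "smoking", "drinking", "bmi")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("covariate file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cov$individual_id))
    stop("duplicate individual_id in covariate file")
  cov$bmi_class <- bmi_class(cov$bmi)
  cov
}

#' BMI obesity classification
#'
#' @param bmi Numeric BMI in kg/m^2.
#' @param cut Obesity threshold, default 28 kg/m^2.
#' @return Factor with levels `"<28"` and `">=28"` (labels follow `cut`).
#' @export
bmi_class <- function(bmi, cut = 28) {
  factor(ifelse(bmi >= cut, paste0(">=", cut), paste0("<", cut)),
         levels = c(paste0("<", cut), paste0(">=", cut)))
}

#' Assemble case-parent triads from pedigree structure
#'
#' One triad is emitted per affected offspring whose mother and father are
#' both genotyped in the dataset. A family with several affected offspring
#' yields one triad per offspring, the triads sharing the same parents.
#' Offspring lacking either parent are excluded and recorded in the
#' `exclusions` attribute. Offspring without a covariate row are retained
#' with covariates flagged missing (they drop out of stratified fits only).
#'
#' @param dataset A [`genotype_dataset`].
#' @param covariates Optional covariate data frame as returned by
#'   [read_covariates()]; keyed by `individual_id`.
#' @return A data frame of class `triad_set` with one row per triad:
#'   `child_id`, `mother_id`, `father_id`, row indices `child_row`,
#'   `mother_row`, `father_row` into the genotype matrix, `affected`, and the
#'   covariates `smoking`, `drinking`, `bmi`, `bmi_class`, `sex` (offspring
#'   sex from the pedigree). Attribute `exclusions` lists offspring excluded
#'   for a missing parent.
#' @export
assemble_triads <- function(dataset, covariates = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  fam <- dataset$fam
  if (anyDuplicated(fam$individual_id)) stop("duplicate individual_id")
  idx <- stats::setNames(seq_len(nrow(fam)), fam$individual_id)

  is_offspring <- fam$father_id != "0" | fam$mother_id != "0"
  affected <- fam$affection == 2L
  kids <- fam[is_offspring & affected, , drop = FALSE]

  have_m <- kids$mother_id %in% fam$individual_id & kids$mother_id != "0"
  have_f <- kids$father_id %in% fam$individual_id & kids$father_id != "0"
  keep <- have_m & have_f
  excl <- kids$individual_id[!keep]
  if (length(excl))
    message(length(excl), " affected offspring excluded (missing parent): ",
            paste(utils::head(excl, 5), collapse = ", "),
            if (length(excl) > 5) ", ..." else "")
  kids <- kids[keep, , drop = FALSE]
  if (any(kids$mother_id == kids$father_id))
    stop("mother and father ids must be distinct samples")

  out <- data.frame(
    child_id = kids$individual_id,
    mother_id = kids$mother_id,
    father_id = kids$father_id,
    child_row = unname(idx[kids$individual_id]),
    mother_row = unname(idx[kids$mother_id]),
    father_row = unname(idx[kids$father_id]),
    sex = kids$sex,
    affected = rep(TRUE, nrow(kids)),
    stringsAsFactors = FALSE
  )
  out$smoking <- rep(NA_integer_, nrow(out))
  out$drinking <- rep(NA_integer_, nrow(out))
  out$bmi <- rep(NA_real_, nrow(out))
  if (!is.null(covariates)) {
    if (anyDuplicated(covariates$individual_id))
      stop("duplicate individual_id in covariates")
    j <- match(out$child_id, covariates$individual_id)
    out$smoking <- covariates$smoking[j]
    out$drinking <- covariates$drinking[j]
    out$bmi <- covariates$bmi[j]
  }
  out$bmi_class <- bmi_class(out$bmi)
  rownames(out) <- NULL
  structure(out, exclusions = excl, class = c("triad_set", "data.frame"))
}

#' Extract the genotype triplets of a triad set at one SNP
#'
#' @param dataset A [`genotype_dataset`].
#' @param triads A `triad_set` from [assemble_triads()].
#' @param snp rsid or column index.
#' @return Integer matrix with columns `g_M`, `g_F`, `g_C` (one row per
#'   triad), the input expected by [fit_poe()].
#' @export
triad_genotypes <- function(dataset, triads, snp) {
  g <- dataset$geno[, snp]
  cbind(g_M = g[triads$mother_row],
        g_F = g[triads$father_row],
        g_C = g[triads$child_row])
}

#' Number of distinct participants in a triad set
#'
#' Parents shared across sibling triads are counted once, so 54 triads drawn
#' from families that include sibling pairs can cover fewer than 162 distinct
#' participants; disjoint families give exactly 3 per triad.
#'
#' @param triads A `triad_set`.
#' @return Integer count of distinct individuals.
#' @export
n_participants <- function(triads) {
  length(unique(c(triads$child_id, triads$mother_id, triads$father_id)))
}
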