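#' Genus rDNA copy-number table
#'
#' ITS2 rDNA copies per cell differ strongly between Symbiodiniaceae
#' genera, biasing raw read proportions toward the high-copy genus. The
#' defaults use the established ratio of 2119 (Cladocopium) to 362
#' (Durusdinium) copies per cell.
#'
#' @param Cladocopium,Durusdinium,other Copies per cell. The `other`
#'   fallback covers unexpected genera.
#' @return Data.frame with columns `genus`, `copies`.
#' @export
copy_number_table <- function(Cladocopium = 2119, Durusdinium = 362,
                              other = 1000) {
  stopifnot(Cladocopium > 0, Durusdinium > 0, other > 0)
  data.frame(genus = c("Cladocopium", "Durusdinium", "other"),
             copies = c(Cladocopium, Durusdinium, other))
}

#' Normalize ITS2 type counts by genus rDNA copy number
#'
#' Converts read counts to relative cell abundances: each type's count is
#' divided by its genus's rDNA copies per cell and the result renormalized
#' to sum to one. Types whose genus is missing from the copy table fall
#' back to the `other` copy number with a warning when present, otherwise
#' the offending types are reported in an error.
#'
#' @param counts Named numeric vector (names = ITS2 types) or data.frame
#'   with columns `its2_type`, `count`.
#' @param genus_map Data.frame with columns `its2_type`, `genus`.
#' @param copies Copy-number table from [copy_number_table()].
#' @return Named numeric vector of relative cell abundances summing to 1.
#' @export
#' @examples
#' copy_number_normalize(c(Ctype = 2119, Dtype = 362),
#'   genus_map = data.frame(its2_type = c("Ctype", "Dtype"),
#'                          genus = c("Cladocopium", "Durusdinium")))
copy_number_normalize <- function(counts, genus_map = default_genus_map(),
                                  copies = copy_number_table()) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$its2_type)
  }
  if (length(counts) == 0L || all(counts == 0)) {
    stop("empty ITS2 profile: no nonzero counts")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  genus <- genus_map$genus[match(names(counts), genus_map$its2_type)]
  if (any(is.na(genus))) {
    stop("no genus mapping for ITS2 type(s): ",
         paste(names(counts)[is.na(genus)], collapse = ", "))
  }
  cpg <- copies$copies[match(genus, copies$genus)]
  if (any(is.na(cpg))) {
    if (!"other" %in% copies$genus) {
      stop("no copy number for genus/genera: ",
           paste(unique(genus[is.na(cpg)]), collapse = ", "))
    }
    warning("genus without copy number, using 'other' fallback: ",
            paste(unique(genus[is.na(cpg)]), collapse = ", "))
    cpg[is.na(cpg)] <- copies$copies[copies$genus == "other"]
  }
  ab <- counts / cpg
  ab / sum(ab)
}

#' Call the dominant symbiont type of a sample
#'
#' The dominant type must strictly exceed the 70 percent abundance
#' threshold; otherwise the sample is called `"mixed"`.
#'
#' @param abundances Named numeric vector summing to 1 (within 1e-9), e.g.
#'   from [copy_number_normalize()].
#' @param threshold Dominance threshold (strict inequality).
#' @return The dominant type name, or `"mixed"`.
#' @export
call_dominant_type <- function(abundances, threshold = 0.70) {
  if (length(abundances) == 0L) stop("empty abundance profile")
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must sum to 1")
  }
  i <- which.max(abundances)
  if (abundances[i] > threshold) names(abundances)[i] else "mixed"
}

#' Dominant-type calls for a whole ITS2 count table
#'
#' @param its2 Data.frame with columns `sample_id`, `its2_type`, `count`.
#' @param genus_map,copies See [copy_number_normalize()].
#' @param normalize Apply copy-number normalization before the dominance
#'   call (the default); `FALSE` applies the threshold to raw read
#'   proportions.
#' @param threshold Dominance threshold.
#' @return Data.frame: sample_id, dominant_type, dominant_abundance.
#' @export
call_dominant_types <- function(its2, genus_map = default_genus_map(),
                                copies = copy_number_table(),
                                normalize = TRUE, threshold = 0.70) {
  out <- lapply(split(its2, its2$sample_id), function(d) {
    x <- stats::setNames(d$count, d$its2_type)
    ab <- if (normalize) {
      copy_number_normalize(x, genus_map, copies)
    } else {
      x / sum(x)
    }
    data.frame(sample_id = d$sample_id[1],
               dominant_type = call_dominant_type(ab, threshold),
               dominant_abundance = max(ab))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
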