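#' Simulate a fermentation experimental design
#'
#' Builds the sample sheet for one of the study arms of an automated in-vitro
#' fermentation screen, assigning reactions to 96-well plates (8 rows x 12
#' columns) under a seeded randomization.
#'
#' Arms:
#' \describe{
#'   \item{population_structure}{full factorial donors x (genotypes + 1 blank
#'     control) x replicates; with 12 donors, 24 genotypes and 3 replicates
#'     this yields 900 reactions.}
#'   \item{mdp_gwas}{augmented partially replicated (p-rep) layout per donor:
#'     a configurable subset of genotypes replicated \code{rep_high} times
#'     (default 7) and the remainder \code{rep_low} times (default 3), plus
#'     \code{blanks_per_plate} blank wells on every plate; digestion batches
#'     group consecutive plates.}
#'   \item{validation_pool, complementation}{pooled pseudo-samples x donors x
#'     replicates; \code{genotypes} is then the vector of pool ids.}
#' }
#'
#' @param arm one of \code{"population_structure"}, \code{"mdp_gwas"},
#'   \code{"validation_pool"}, \code{"complementation"}.
#' @param donors character vector of donor (microbiome) ids.
#' @param genotypes character vector of line ids (or pool ids for the pooled
#'   arms).
#' @param replicates technical replicates per genotype (population_structure
#'   and pooled arms).
#' @param n_high number of genotypes replicated at the high rate in the
#'   p-rep arm (taken from the head of a seeded permutation of
#'   \code{genotypes}).
#' @param rep_high,rep_low replicate counts for the p-rep arm.
#' @param blanks_per_plate blank control wells per plate.
#' @param plates_per_batch consecutive plates per in-vitro digestion batch.
#' @param max_plates optional cap on plates per donor; exceeding it is an
#'   error (plate capacity exceeded).
#' @param seed integer seed for randomization of wells.
#'
#' @return data.frame with columns \code{sample_id}, \code{donor_id},
#'   \code{line_id} (\code{"BLANK"} for controls), \code{technical_replicate},
#'   \code{digestion_batch}, \code{plate_id}, \code{plate_row} (A-H),
#'   \code{plate_column} (1-12), \code{design_arm}.
#' @export
simulate_fermentation_design <- function(arm = c("population_structure", "mdp_gwas",
                                                 "validation_pool", "complementation"),
                                         donors,
                                         genotypes,
                                         replicates = 3L,
                                         n_high = 0L,
                                         rep_high = 7L,
                                         rep_low = 3L,
                                         blanks_per_plate = 1L,
                                         plates_per_batch = 4L,
                                         max_plates = Inf,
                                         seed = 1L) {
  arm <- match.arg(arm)
  if (length(genotypes) == 0) stop("at least one genotype (or pool) is required")
  if (length(donors) == 0) stop("at least one donor is required")

  with_seed(seed, {
    rows <- lapply(donors, function(d) {
      if (arm == "population_structure" || arm %in% c("validation_pool", "complementation")) {
        ids <- c(genotypes, if (arm == "population_structure") "BLANK")
        per <- rep(ids, each = replicates)
        reps <- rep(seq_len(replicates), times = length(ids))
      } else { # mdp_gwas p-rep
        if (n_high > length(genotypes)) stop("n_high exceeds number of genotypes")
        perm <- sample(genotypes)
        high <- perm[seq_len(n_high)]
        low <- setdiff(perm, high)
        per <- c(rep(high, each = rep_high), rep(low, each = rep_low))
        reps <- c(rep(seq_len(rep_high), times = length(high)),
                  rep(seq_len(rep_low), times = length(low)))
      }
      df <- data.frame(donor_id = d, line_id = per, technical_replicate = reps,
                       stringsAsFactors = FALSE)

      # plate assignment: fill 96-well plates, reserving blank wells per plate
      # in the p-rep arm; order randomized within donor
      wells_per_plate <- 96L
      usable <- if (arm == "mdp_gwas") wells_per_plate - blanks_per_plate else wells_per_plate
      if (usable <= 0) stop("blanks_per_plate leaves no usable wells")
      n_plates <- ceiling(nrow(df) / usable)
      if (n_plates > max_plates) {
        stop(sprintf("plate capacity exceeded: need %d plates, max_plates = %s",
                     n_plates, format(max_plates)))
      }
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      plate_of <- rep(seq_len(n_plates), each = usable)[seq_len(nrow(df))]
      if (arm == "mdp_gwas" && blanks_per_plate > 0) {
        blanks <- data.frame(donor_id = d,
                             line_id = "BLANK",
                             technical_replicate = rep(seq_len(blanks_per_plate), n_plates),
                             stringsAsFactors = FALSE)
        df <- rbind(df, blanks)
        plate_of <- c(plate_of, rep(seq_len(n_plates), each = blanks_per_plate))
      }
      df$plate_id <- paste0(d, "_P", plate_of)

      # randomize wells within each plate
      out <- do.call(rbind, lapply(split(df, df$plate_id), function(pd) {
        w <- sample.int(wells_per_plate, nrow(pd))
        pd$plate_row <- LETTERS[(w - 1L) %/% 12L + 1L]
        pd$plate_column <- (w - 1L) %% 12L + 1L
        pd
      }))
      pl <- as.integer(sub(".*_P", "", out$plate_id))
      out$digestion_batch <- paste0(d, "_B", (pl - 1L) %/% plates_per_batch + 1L)
      out
    })
    design <- do.call(rbind, rows)
    design$design_arm <- arm
    design$sample_id <- sprintf("S%05d", seq_len(nrow(design)))
    rownames(design) <- NULL
    design[, c("sample_id", "donor_id", "line_id", "technical_replicate",
               "digestion_batch", "plate_id", "plate_row", "plate_column",
               "design_arm")]
  })
}
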