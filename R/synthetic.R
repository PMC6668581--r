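#' @include AllClasses.R
NULL

#' Construct a synthetic-fixture specification
#'
#' Defaults encode the presequence architecture the toolkit targets:
#' plastid proteins carry a bipartite targeting signal — an ER signal
#' peptide (16-28 residues) directly followed by a transit peptide, the
#' whole N-terminal extension spanning 40-80 residues — with
#' phenylalanine at the first mature position (+1) with probability 0.8
#' under the \code{cvelia_like} profile and 0.5 under
#' \code{vbrassicaformis_like}; mitochondrial presequences are shorter
#' (15-40 residues) and arginine-rich; secretory proteins carry the
#' signal peptide only; cytosolic proteins no presequence at all.
#'
#' @param nPerClass proteins per compartment class.
#' @param seed RNG seed.
#' @param speciesProfile \code{"cvelia_like"} or
#'   \code{"vbrassicaformis_like"}.
#' @param phePlus1Prob probability of Phe at +1 for plastid proteins;
#'   defaults to 0.8 (cvelia_like) or 0.5 (vbrassicaformis_like).
#' @param signalLenRange signal-peptide length range.
#' @param btsExtensionRange total plastid N-terminal extension range.
#' @param mitoPresequenceRange mitochondrial presequence length range.
#' @param matureLenRange mature-domain length range.
#' @param background per-residue background frequency (default uniform).
#' @return a validated \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(nPerClass = 200L, seed = 1L,
                        speciesProfile = c("cvelia_like",
                                           "vbrassicaformis_like"),
                        phePlus1Prob = NULL,
                        signalLenRange = c(16L, 28L),
                        btsExtensionRange = c(40L, 80L),
                        mitoPresequenceRange = c(15L, 40L),
                        matureLenRange = c(150L, 400L),
                        background = NULL) {
  speciesProfile <- match.arg(speciesProfile)
  if (is.null(phePlus1Prob))
    phePlus1Prob <- if (speciesProfile == "cvelia_like") 0.8 else 0.5
  if (is.null(background)) background <- .uniformBackground()
  new("FixtureSpec", nPerClass = as.integer(nPerClass),
      seed = as.integer(seed), speciesProfile = speciesProfile,
      phePlus1Prob = as.numeric(phePlus1Prob),
      signalLenRange = as.integer(signalLenRange),
      btsExtensionRange = as.integer(btsExtensionRange),
      mitoPresequenceRange = as.integer(mitoPresequenceRange),
      matureLenRange = as.integer(matureLenRange),
      background = background[AA20])
}

.sampleBg <- function(n, background) {
  if (n <= 0L) return(character(0))
  sample(AA20, n, replace = TRUE, prob = background)
}

.rint <- function(range) {
  if (range[1] == range[2]) range[1]
  else sample(range[1]:range[2], 1L)
}

## classic tripartite signal peptide: Met + short charged/neutral n-region
## + hydrophobic h-region + c-region obeying the (-3, -1) small-residue
## rule: Ala dominates the -1 and -3 positions of the scissile bond while
## the rest of the c-region avoids Ala, which is what makes the cleavage
## site positionally well-defined
.signalPeptide <- function(totalLen) {
  nRegAA <- c("K", "R", "Q", "N", "S", "T", "G", "A")
  hRegAA <- c("A", "L", "I", "V", "F", "W", "M")
  cRegAA <- c("S", "G", "T", "P", "Q", "V")
  repeat {
    nLen <- .rint(c(1L, 5L))
    hLen <- .rint(c(7L, 13L))
    cLen <- totalLen - 1L - nLen - hLen
    if (cLen >= 3L) break
  }
  cReg <- sample(cRegAA, cLen, replace = TRUE)
  cReg[cLen] <- if (stats::runif(1) < 0.85) "A"
                else sample(c("G", "S"), 1L)
  cReg[cLen - 2L] <- if (stats::runif(1) < 0.7) "A" else "V"
  c("M", sample(nRegAA, nLen, replace = TRUE),
    sample(hRegAA, hLen, replace = TRUE), cReg)
}

## transit-peptide segment: hydroxylated/basic enrichment (S/T/R combined
## frequency 0.45), remainder background-proportional
.transitSegment <- function(n, background) {
  if (n <= 0L) return(character(0))
  prob <- background
  prob[c("S", "T", "R")] <- 0
  prob <- prob / sum(prob) * 0.55
  prob[c("S", "T", "R")] <- c(0.18, 0.15, 0.12)
  sample(AA20, n, replace = TRUE, prob = prob[AA20])
}

## mitochondrial presequence: Arg-rich (0.25), devoid of acidic residues
.mitoPresequence <- function(n, background) {
  prob <- background
  prob[c("D", "E", "R")] <- 0
  prob <- prob / sum(prob) * 0.75
  prob["R"] <- 0.25
  sample(AA20, n, replace = TRUE, prob = prob[AA20])
}

#' Generate a labelled synthetic protein fixture
#'
#' Deterministically (given the seed) generates \code{nPerClass} proteins
#' per compartment class, together with a truth table recording the class
#' label and, for the signal-peptide-bearing classes (plastid and
#' secretory), the exact cleavage position (last signal-peptide residue).
#'
#' Plastid proteins: signal peptide, then a transit peptide starting at
#' +1 with Phe with probability \code{phePlus1Prob} (else a non-Phe
#' background residue, so the probability is exact), S/T/R-enriched up to
#' the drawn bipartite-extension length, then a background-sampled mature
#' domain. Secretory: the same signal peptide followed directly by a
#' background mature domain. Mitochondrion: Met + Arg-rich presequence
#' without acidic residues + background mature domain. Cytosol: Met +
#' background mature domain.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @return a list with \code{sequences} (an \code{AAStringSet}) and
#'   \code{truth} (data.frame with columns \code{id}, \code{label},
#'   \code{known_cleavage}).
#' @export
generateFixture <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec@seed)
  bg <- spec@background
  n <- spec@nPerClass
  seqs <- character(0)
  ids <- character(0)
  labels <- character(0)
  cleav <- integer(0)
  emit <- function(id, label, residues, kc) {
    seqs <<- c(seqs, paste(residues, collapse = ""))
    ids <<- c(ids, id)
    labels <<- c(labels, label)
    cleav <<- c(cleav, kc)
  }
  for (i in seq_len(n)) {
    ## plastid: signal + transit (bipartite extension) + mature
    sigLen <- .rint(spec@signalLenRange)
    extLen <- max(.rint(spec@btsExtensionRange), sigLen + 5L)
    sig <- .signalPeptide(sigLen)
    plus1 <- if (stats::runif(1) < spec@phePlus1Prob) "F"
             else sample(setdiff(AA20, "F"), 1L,
                         prob = bg[setdiff(AA20, "F")] /
                                sum(bg[setdiff(AA20, "F")]))
    transit <- c(plus1, .transitSegment(extLen - sigLen - 1L, bg))
    mature <- .sampleBg(.rint(spec@matureLenRange), bg)
    emit(sprintf("pla_%04d", i), "plastid", c(sig, transit, mature),
         sigLen)
    ## secretory: signal + mature
    sigLen <- .rint(spec@signalLenRange)
    sig <- .signalPeptide(sigLen)
    mature <- .sampleBg(.rint(spec@matureLenRange), bg)
    emit(sprintf("sec_%04d", i), "secretory", c(sig, mature), sigLen)
    ## mitochondrion: Met + Arg-rich presequence + mature
    preLen <- .rint(spec@mitoPresequenceRange)
    pre <- .mitoPresequence(preLen, bg)
    mature <- .sampleBg(.rint(spec@matureLenRange), bg)
    emit(sprintf("mit_%04d", i), "mitochondrion", c("M", pre, mature),
         NA_integer_)
    ## cytosol: Met + mature only
    mature <- .sampleBg(.rint(spec@matureLenRange), bg)
    emit(sprintf("cyt_%04d", i), "cytosol", c("M", mature), NA_integer_)
  }
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- ids
  S4Vectors::mcols(aa) <- S4Vectors::DataFrame(
    description = sprintf("synthetic %s (%s)", labels,
                          spec@speciesProfile),
    chimeric = rep(FALSE, length(aa)),
    source = rep(sprintf("synthetic:%s:seed%d", spec@speciesProfile,
                         spec@seed), length(aa)))
  list(sequences = aa,
       truth = data.frame(id = ids, label = labels,
                          known_cleavage = cleav,
                          stringsAsFactors = FALSE))
}

#' Turn a generated fixture into a ReferenceSet
#'
#' @param fixture the list returned by \code{\link{generateFixture}}.
#' @return a \linkS4class{ReferenceSet} with the truth labels and known
#'   cleavage positions.
#' @export
fixtureReferenceSet <- function(fixture) {
  referenceSet(fixture$sequences, id = fixture$truth$id,
               label = fixture$truth$label,
               knownCleavage = fixture$truth$known_cleavage)
}

#' Write a fixture to disk
#'
#' Writes the FASTA file (\code{sequences.faa}) and the truth table
#' (\code{truth.tsv}, columns id / label / known_cleavage) into a
#' directory.
#'
#' @param fixture the list returned by \code{\link{generateFixture}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFastaProteins(fixture$sequences, file.path(dir, "sequences.faa"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
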