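#' Default position-weight table for the efficiency scorer
#'
#' A simple, fully documented heuristic table for ranking guides within a
#' target region. Columns are protospacer positions 1 (PAM-distal) to 20
#' (PAM-proximal); rows are A, C, G, T. The shipped weights encode three
#' widely used rules of thumb for SpCas9 on-target activity: a G immediately
#' 5' of the PAM (position 20) is favoured and a T there strongly
#' disfavoured; T runs in the PAM-proximal half depress activity (mild T
#' penalty over positions 15-19); and moderate G/C content in the seed is
#' preferred (small G/C bonus over positions 13-18). The table is a
#' placeholder for whatever model a user trusts: any complete 4 x 20 matrix
#' can be passed to \code{\link{GuideDesignParam}}, so published scoring
#' models can be dropped in without touching the screening code.
#'
#' @return a 4 x 20 numeric matrix with rows A, C, G, T.
#' @examples
#' w <- defaultEfficiencyWeights()
#' w["G", 20]   # the strongest single weight
#' @export
defaultEfficiencyWeights <- function() {
    w <- matrix(0, nrow = 4L, ncol = 20L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    w["G", 20L] <- 1.0
    w["C", 20L] <- 0.3
    w["T", 20L] <- -0.8
    w["T", 15:19] <- -0.2
    w[c("G", "C"), 13:18] <- w[c("G", "C"), 13:18] + 0.15
    w
}

#' Construct a screening/design parameter set
#'
#' All defaults correspond to the design rules this package implements:
#' ~100 bp target regions, 20-nt protospacers with NGG on-target PAMs, an
#' off-target defined as any NGG/NAG site with no mismatch in the 12-nt
#' PAM-proximal seed and at most 3 mismatches overall, a minimum cut
#' separation of 200 bp, and a 5 kb ceiling for a detectable PCR product.
#'
#' @param windowLength target-region length in bp.
#' @param minWindow smallest acceptable clipped region in bp.
#' @param pamSlack bp the PAM may extend past the region edge.
#' @param maxMMTotal maximum protospacer mismatches for an off-target call.
#' @param maxMMSeed maximum mismatches in the 12-nt seed for an off-target
#'   call.
#' @param offtargetPAMs PAM classes admitted as off-target sites.
#' @param minSeparation minimum distance between the two cuts in bp.
#' @param efficiencyFloor minimum efficiency score for PASS (default 0:
#'   efficiency ranks candidates but rejects none).
#' @param efficiencyWeights 4 x 20 weight matrix (rows A,C,G,T).
#' @param maxAmplifiable largest product size called detectable, bp.
#' @param warnAmplifiable borderline-detectable ceiling, bp.
#' @param nAlternates number of runner-up guide pairs to keep.
#' @return a \linkS4class{GuideDesignParam}.
#' @examples
#' GuideDesignParam(minSeparation = 400L)
#' @export
GuideDesignParam <- function(windowLength = 100L, minWindow = 30L,
                             pamSlack = 3L, maxMMTotal = 3L, maxMMSeed = 0L,
                             offtargetPAMs = c("NGG", "NAG"),
                             minSeparation = 200L, efficiencyFloor = 0,
                             efficiencyWeights = defaultEfficiencyWeights(),
                             maxAmplifiable = 5000L, warnAmplifiable = 10000L,
                             nAlternates = 5L) {
    new("GuideDesignParam",
        windowLength = as.integer(windowLength),
        minWindow = as.integer(minWindow),
        spacerLength = 20L,
        pamSlack = as.integer(pamSlack),
        maxMMTotal = as.integer(maxMMTotal),
        maxMMSeed = as.integer(maxMMSeed),
        offtargetPAMs = offtargetPAMs,
        minSeparation = as.integer(minSeparation),
        efficiencyFloor = as.numeric(efficiencyFloor),
        efficiencyWeights = efficiencyWeights,
        maxAmplifiable = as.integer(maxAmplifiable),
        warnAmplifiable = as.integer(warnAmplifiable),
        nAlternates = as.integer(nAlternates))
}

# flat named list used to embed the parameter snapshot in reports
paramAsList <- function(param) {
    list(windowLength = param@windowLength, minWindow = param@minWindow,
         spacerLength = param@spacerLength, pamSlack = param@pamSlack,
         maxMMTotal = param@maxMMTotal, maxMMSeed = param@maxMMSeed,
         offtargetPAMs = paste(param@offtargetPAMs, collapse = ","),
         minSeparation = param@minSeparation,
         efficiencyFloor = param@efficiencyFloor,
         efficiencyWeightsDigest = digestMatrix(param@efficiencyWeights),
         maxAmplifiable = param@maxAmplifiable,
         warnAmplifiable = param@warnAmplifiable,
         nAlternates = param@nAlternates)
}

digestMatrix <- function(m) {
    # cheap stable fingerprint: dimensions + rounded checksum of entries
    sprintf("%dx%d:%.6f", nrow(m), ncol(m), sum(m * seq_along(m)))
}
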