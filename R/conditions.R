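# Classed conditions so callers can distinguish design failures from bugs.

designError <- function(class, msg, ...) {
    structure(
        class = c(class, "dgRNAdesignError", "error", "condition"),
        list(message = msg, call = sys.call(-1), ...)
    )
}

stopNoCleanRegion <- function(gene, role, blockers) {
    stop(designError("NoCleanRegion",
        sprintf("gene '%s': no %s window of minimum length avoids foreign CDS (blocking gene%s: %s)",
                gene, role, if (length(blockers) == 1L) "" else "s",
                paste(blockers, collapse = ", ")),
        gene = gene, role = role, blockers = blockers))
}

stopNoViablePair <- function(gene, stage, msg) {
    stop(designError("NoViablePair",
        sprintf("gene '%s': no viable guide pair (failing stage: %s) - %s",
                gene, stage, msg),
        gene = gene, stage = stage))
}

stopInputError <- function(class, msg) stop(designError(class, msg))
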