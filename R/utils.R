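# Internal helpers shared across modules.

# Gene symbols are matched case-insensitively after trimming whitespace;
# the canonical form is the trimmed upper-case symbol. Cross-study merges in
# this field are done on bare symbols with no identifier mapping, so this is
# the only normalization applied.
normalize_symbols <- function(x) toupper(trimws(x))

stop_config <- function(field, why) {
    stop(sprintf("invalid configuration field '%s': %s", field, why),
         call. = FALSE)
}

# group means of columns of a matrix; returns genes x groups
group_col_means <- function(m, groups) {
    g <- factor(groups)
    sapply(levels(g), function(l)
        rowMeans(m[, groups == l, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
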