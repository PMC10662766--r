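#' @keywords internal
"_PACKAGE"

## RNA alphabet used throughout; DNA input (T) is mapped to U on entry.
RNA_BASES <- c("A", "C", "G", "U")
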