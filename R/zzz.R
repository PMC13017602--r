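#' @keywords internal
#' @importFrom data.table data.table as.data.table setorder rbindlist fread
#' @importFrom stats qnorm pnorm qlnorm plnorm qgamma qpois qlogis plogis
"_PACKAGE"

## let data.table's non-standard evaluation work inside this package
.datatable.aware <- TRUE
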