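# shared column/event vocabulary (defined first in collation order)
.GAS_COLS <- c("x_CO", "x_CO2", "x_H2", "x_CH4", "x_N2")
.EVENT_KINDS <- c("gas_sample", "liquid_sample", "flush")
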