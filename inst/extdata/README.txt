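Synthetic example logger exports (generated by the package's own scenario
generator, summer preset, seed 314, 15-minute sampling). One variable per
file, miniDOT/HOBO-style layout: timestamp column plus a value column.
These are demonstration inputs for read_sensor_file()/assemble_forcing();
they are not field data.
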