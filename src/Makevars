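# FP contraction off so the compiled tracer is bit-reproducible against the
# scalar R reference tracer that shares its random stream.
PKG_CXXFLAGS = -ffp-contract=off
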