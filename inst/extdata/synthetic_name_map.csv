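"synonym","accepted"
"Oldgenus oldspecies","Genus10 sp06"
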