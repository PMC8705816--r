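keyword	module
integrase	integration_excision
recombinase	integration_excision
excisionase	integration_excision
holin	lysis
endolysin	lysis
lysin	lysis
lysozyme	lysis
primase	dna_replication
helicase	dna_replication
polymerase	dna_replication
replication	dna_replication
single-stranded DNA-binding	dna_replication
capsid	head_tail
head	head_tail
tail	head_tail
baseplate	head_tail
tape measure	head_tail
scaffolding	head_tail
terminase	dna_packaging
portal	dna_packaging
packaging	dna_packaging
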