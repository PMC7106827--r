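EOG09F00001	Development
EOG09F00001	Signaling
EOG09F00002	Development
EOG09F00003	Metabolism
EOG09F00003	Development
EOG09F00004	Signaling
EOG09F00005	Immune
EOG09F00005	Signaling
EOG09F00005	Development
EOG09F00006	Metabolism
EOG09F00007	Transport
EOG09F00008	Development
EOG09F00009	Immune
EOG09F00010	Structure
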