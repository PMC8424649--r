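>FAN1_Nterm_synthetic synthetic FAN1-like 200-mer; SPYF placed at 126-129; not the UniProt Q9Y2M0 sequence
FIKDGTMCKHEFDLRWVCLQNKKTWVNKYFCMLHWGMDFCCKVKAQERIVCHSRSVTNFNYHGYLYWYMEAAMGWSITHMWMLVTYKMGSNCCFDGRLLVFTTNGQECTRGSIYVTGTVYGWSSISPYFMYVVTSQKSWWKFIYNMRCDREELCLSGLYTKIGACHCTRALGFHCCIDAASHSICKSSAYINLWFKTVCT
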