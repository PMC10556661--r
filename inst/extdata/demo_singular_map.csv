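plural,singular
dogs,dog
cats,cat
birds,robin
mice,mouse
rats,rat
cows,cow
frogs,frog
snakes,snake
worms,worm
bees,bee
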