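# Demonstration animal class scheme (English), item,class — one row per membership.
# Classes outside the twelve taxonomic ones (e.g. pets) are mere clusters.
robin,Bird
sparrow,Bird
eagle,Bird
pigeon,Bird
seagull,Bird
owl,Bird
blackbird,Bird
magpie,Bird
heron,Bird
swan,Bird
duck,Bird
goose,Bird
salmon,Fish
herring,Fish
cod,Fish
eel,Fish
pike,Fish
carp,Fish
trout,Fish
tuna,Fish
plaice,Fish
shark,Fish
ant,Insects
bee,Insects
wasp,Insects
beetle,Insects
butterfly,Insects
fly,Insects
mosquito,Insects
grasshopper,Insects
cow,Bovine
bull,Bovine
ox,Bovine
bison,Bovine
buffalo,Bovine
dog,Canine
wolf,Canine
fox,Canine
jackal,Canine
cat,Feline
lion,Feline
tiger,Feline
leopard,Feline
lynx,Feline
deer,Deers
elk,Deers
moose,Deers
reindeer,Deers
roe,Deers
monkey,Primates
gorilla,Primates
chimpanzee,Primates
orangutan,Primates
baboon,Primates
snake,Reptile/Amphibian
lizard,Reptile/Amphibian
frog,Reptile/Amphibian
toad,Reptile/Amphibian
salamander,Reptile/Amphibian
crocodile,Reptile/Amphibian
turtle,Reptile/Amphibian
mouse,Rodents
rat,Rodents
squirrel,Rodents
hamster,Rodents
beaver,Rodents
guinea pig,Rodents
weasel,Weasels
ferret,Weasels
otter,Weasels
badger,Weasels
marten,Weasels
seal,Weasels
seal,Fish
worm,Worms
earthworm,Worms
leech,Worms
caterpillar,Worms
caterpillar,Insects
dog,pets
cat,pets
hamster,pets
guinea pig,pets
lion,zoo animals
tiger,zoo animals
gorilla,zoo animals
crocodile,zoo animals
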